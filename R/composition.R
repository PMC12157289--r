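# Food-composition data model and protein-quality arithmetic.
#
# Amino-acid content is keyed per gram of protein (mg AA / g protein) rather
# than per 100 g food, so that rescaling a reference AA profile to the locally
# reported protein content of a food is a single multiplication. True ileal
# digestibility (TID) coefficients are properties of each composition row.

#' Construct an empty nutrient vector
#'
#' A nutrient vector is a named numeric vector with components
#' \code{protein} and the seven tracked IAAs, all in grams. It supports
#' ordinary componentwise addition and scalar scaling.
#'
#' @param protein Protein, g.
#' @param iaa Named numeric vector of IAA amounts in g; missing names are 0.
#' @return Named numeric vector over [NUTRIENT_NAMES].
#' @export
#' @examples
#' nutrient_vector(protein = 10, iaa = c(lysine = 0.5))
nutrient_vector <- function(protein = 0, iaa = numeric(0)) {
  v <- setNames(numeric(length(NUTRIENT_NAMES)), NUTRIENT_NAMES)
  v["protein"] <- protein
  if (length(iaa)) {
    bad <- setdiff(names(iaa), IAA_NAMES)
    if (length(bad))
      stop("unknown amino acid name(s): ", paste(bad, collapse = ", "))
    v[names(iaa)] <- iaa
  }
  if (any(v < 0)) stop("nutrient components must be nonnegative")
  v
}

#' Rescale a reference amino-acid profile to local protein content
#'
#' Reference AA profiles (e.g. from a foreign food-composition database) are
#' expressed per gram of protein; the amount of each amino acid supplied by a
#' consumed food is approximated by multiplying that profile by the locally
#' reported protein content of the food.
#'
#' @param reference_iaa_per_g_protein Named numeric vector, mg AA per g
#'   protein; names must be a subset of [IAA_NAMES].
#' @param local_protein Protein content the profile is scaled to, g.
#' @return Named numeric vector of amino-acid amounts in g (mg converted to g).
#' @export
#' @examples
#' normalise_aa(c(lysine = 50), local_protein = 25)  # 1.25 g lysine
normalise_aa <- function(reference_iaa_per_g_protein, local_protein) {
  if (!is.numeric(local_protein) || length(local_protein) != 1L ||
      is.na(local_protein) || local_protein < 0)
    stop("local_protein must be a single nonnegative number")
  if (any(reference_iaa_per_g_protein < 0, na.rm = TRUE))
    stop("reference amino-acid contents must be nonnegative")
  bad <- setdiff(names(reference_iaa_per_g_protein), IAA_NAMES)
  if (length(bad))
    stop("unknown amino acid name(s): ", paste(bad, collapse = ", "))
  reference_iaa_per_g_protein * local_protein / 1000
}

#' Adjust a nutrient vector for true ileal digestibility
#'
#' Multiplies every component by its TID coefficient, giving the utilisable
#' (absorbed at the terminal ileum) amount. Every nonzero component must have
#' a coefficient; a missing coefficient is an error rather than a silent
#' pass-through.
#'
#' @param raw Nutrient vector (see [nutrient_vector()]), g.
#' @param tid Named numeric vector of digestibility fractions in \[0, 1\];
#'   names over \code{protein} and the IAAs.
#' @return TID-adjusted nutrient vector, g.
#' @export
#' @examples
#' apply_tid(nutrient_vector(protein = 10, iaa = c(leucine = 0.8)),
#'           c(protein = 0.9, leucine = 0.75))
apply_tid <- function(raw, tid) {
  if (any(tid < 0 | tid > 1, na.rm = TRUE))
    stop("TID fractions must lie in [0, 1]")
  nz <- names(raw)[!is.na(raw) & raw > 0]
  missing_tid <- setdiff(nz, names(tid)[!is.na(tid)])
  if (length(missing_tid))
    stop("missing TID coefficient for nonzero component(s): ",
         paste(missing_tid, collapse = ", "))
  out <- raw
  idx <- intersect(names(raw), names(tid))
  out[idx] <- raw[idx] * tid[idx]
  out
}

# Column layout of a composition table (wide CSV form).
composition_columns <- function() {
  c("food_id", "food_group", "protein_per_100g",
    paste0("aa_", IAA_NAMES, "_mg_per_g_protein"),
    "tid_protein", paste0("tid_", IAA_NAMES))
}

#' Validate a food-composition table
#'
#' Checks the strict wide layout: \code{food_id}, \code{food_group},
#' \code{protein_per_100g}, one \code{aa_<name>_mg_per_g_protein} column and
#' one \code{tid_<name>} column per tracked IAA, plus \code{tid_protein}.
#'
#' @param composition Data frame.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_composition <- function(composition) {
  need <- composition_columns()
  missing_cols <- setdiff(need, names(composition))
  if (length(missing_cols))
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(composition) == 0L)
    stop("composition table is empty")
  if (anyDuplicated(composition$food_id))
    stop("composition table has duplicated food_id values")
  if (any(composition$protein_per_100g < 0))
    stop("protein_per_100g must be nonnegative")
  tid_cols <- c("tid_protein", paste0("tid_", IAA_NAMES))
  tid_vals <- as.matrix(composition[tid_cols])
  if (any(tid_vals < 0 | tid_vals > 1, na.rm = TRUE))
    stop("TID fractions must lie in [0, 1]")
  composition
}

# Extract the AA profile (mg/g protein) and TID map for one composition row.
entry_profile <- function(entry) {
  aa <- as.numeric(entry[paste0("aa_", IAA_NAMES, "_mg_per_g_protein")])
  names(aa) <- IAA_NAMES
  tid <- as.numeric(entry[c("tid_protein", paste0("tid_", IAA_NAMES))])
  names(tid) <- c("protein", IAA_NAMES)
  list(aa = aa, tid = tid)
}

#' Nutrients supplied by an amount of one food
#'
#' Protein is \code{protein_per_100g * amount_g / 100}; amino acids follow by
#' rescaling the food's AA profile to that protein ([normalise_aa()]); the
#' whole vector is then digestibility-adjusted ([apply_tid()]) unless
#' \code{adjust = FALSE}.
#'
#' @param entry One row of a validated composition table (data frame row or
#'   named list).
#' @param amount_g Consumed amount, g.
#' @param adjust Apply TID adjustment (default TRUE).
#' @return Nutrient vector in g.
#' @export
#' @examples
#' comp <- synthetic_composition()
#' nutrient_for_item(comp[comp$food_id == "tofu_firm", ], 150)
nutrient_for_item <- function(entry, amount_g, adjust = TRUE) {
  if (!is.numeric(amount_g) || length(amount_g) != 1L || is.na(amount_g) ||
      amount_g < 0)
    stop("amount_g must be a single nonnegative number")
  entry <- as.list(entry)
  prof <- entry_profile(entry)
  protein <- as.numeric(entry$protein_per_100g) * amount_g / 100
  raw <- nutrient_vector(protein = protein,
                         iaa = normalise_aa(prof$aa, protein))
  if (!adjust) return(raw)
  apply_tid(raw, prof$tid)
}

#' Read a composition table from CSV
#'
#' @param path CSV path with the strict wide header (see
#'   [validate_composition()]).
#' @return Validated composition data frame.
#' @export
read_composition <- function(path) {
  validate_composition(read.csv(path, stringsAsFactors = FALSE))
}
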