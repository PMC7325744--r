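#' Read a long-format field book
#'
#' The canonical field-book dialect is tidy/long: one row per plot per
#' trait, columns `location`, `block`, `genotype`, `maternal`, `paternal`,
#' `trait`, `value`. `maternal`/`paternal` may be empty for non-hybrid
#' entries (inbred checks). Proportion traits are stored internally in
#' [0, 1]; a trait name carrying a `%` suffix (e.g. `germination%`) is
#' accepted and its values divided by 100 at ingest.
#'
#' @param path CSV file path.
#' @param traits A `trait_spec` data frame declaring the known trait names;
#'   defaults to [default_trait_specs()]. Unknown trait names are rejected.
#' @return A `fieldbook` data frame of typed plot observations.
#' @export
read_fieldbook <- function(path, traits = default_trait_specs()) {
  if (!file.exists(path)) stop("field book not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("location", "block", "genotype", "trait", "value")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("field book lacks required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  for (col in c("maternal", "paternal"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !(is.na(df$value) | df$value == ""))
  if (length(bad))
    stop("non-numeric trait value at data row ", bad[1],
         " ('", df$value[bad[1]], "')", call. = FALSE)
  df$value <- val
  # percent-suffixed trait names -> internal proportion unit
  pct <- grepl("%$", df$trait)
  df$trait[pct] <- sub("%$", "", df$trait[pct])
  df$value[pct] <- df$value[pct] / 100
  df$maternal[df$maternal == ""] <- NA_character_
  df$paternal[df$paternal == ""] <- NA_character_
  out <- df[, c("location", "block", "genotype", "maternal", "paternal",
                "trait", "value")]
  validate_fieldbook(out, traits)
}

#' @keywords internal
validate_fieldbook <- function(fb, traits = default_trait_specs()) {
  unknown <- setdiff(unique(fb$trait), traits$name)
  if (length(unknown))
    stop("unknown trait name(s): ", paste(unknown, collapse = ", "),
         "; declare them in the config to accept", call. = FALSE)
  reg <- trait_registry()
  kind <- reg$kind[match(fb$trait, reg$name)]
  kind[is.na(kind)] <- "continuous"
  ok <- !is.na(fb$value)
  prop_bad <- ok & kind == "proportion" & (fb$value < 0 | fb$value > 1)
  if (any(prop_bad))
    stop("proportion trait outside [0, 1]: ",
         fb$trait[which(prop_bad)[1]], " = ",
         fb$value[which(prop_bad)[1]], call. = FALSE)
  score_bad <- ok & kind == "score" & (fb$value < 1 | fb$value > 7)
  if (any(score_bad))
    stop("vitreousness score outside [1, 7]", call. = FALSE)
  count_bad <- ok & kind == "count" & fb$value < 0
  if (any(count_bad))
    stop("count trait is negative: ", fb$trait[which(count_bad)[1]],
         call. = FALSE)
  class(fb) <- c("fieldbook", "data.frame")
  fb
}

#' Write a field book to CSV
#' @param fb A `fieldbook` data frame.
#' @param path Output CSV path.
#' @export
write_fieldbook <- function(fb, path) {
  utils::write.csv(as.data.frame(fb), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree table
#'
#' Columns: `inbred`, `qpm_parent`, `popcorn_parent`, `heterotic_pool`
#' (the pool of the popcorn parent). Each inbred must appear exactly once.
#'
#' @param path CSV file path.
#' @return A `pedigree` data frame.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) {
    warning("empty pedigree file: ", path)
    df <- data.frame(inbred = character(), qpm_parent = character(),
                     popcorn_parent = character(),
                     heterotic_pool = character(), stringsAsFactors = FALSE)
    class(df) <- c("pedigree", "data.frame")
    return(df)
  }
  required <- c("inbred", "qpm_parent", "popcorn_parent", "heterotic_pool")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("pedigree lacks required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  validate_pedigree(df[, required])
}

#' @keywords internal
validate_pedigree <- function(ped) {
  dup <- ped$inbred[duplicated(ped$inbred)]
  if (length(dup))
    stop("duplicate inbred id in pedigree: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  pool_by_pop <- tapply(ped$heterotic_pool, ped$popcorn_parent,
                        function(x) length(unique(x)))
  if (any(pool_by_pop > 1))
    stop("a popcorn parent maps to more than one heterotic pool", call. = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write a pedigree table to CSV
#' @param ped A `pedigree` data frame.
#' @param path Output CSV path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE)
  invisible(path)
}

#' Read an amino-acid profile table
#'
#' Columns: `genotype`, `class` (one of `QPP_hybrid`, `QPP_inbred`,
#' `popcorn`, `QPM`, `dent_check`), `residue`, `fraction` (`protein_bound`
#' or `free`), `treatment` (`raw`, `air`, `microwave`, `oil`), `replicate`,
#' `value` (g / 100 g). Acid hydrolysis destroys tryptophan and cysteine,
#' so those residues may never appear in the `protein_bound` fraction;
#' the composite residues `Asx` (Asp+Asn) and `Glx` (Glu+Gln) are
#' first-class codes in bound-fraction data.
#'
#' @param path CSV file path.
#' @return An `amino_profile` data frame.
#' @export
read_amino_profiles <- function(path) {
  if (!file.exists(path)) stop("amino-acid file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("genotype", "class", "residue", "fraction", "treatment",
                "replicate", "value")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("amino-acid table lacks required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value))
    stop("non-numeric amino-acid value at data row ",
         which(is.na(df$value))[1], call. = FALSE)
  validate_amino_profiles(df[, required])
}

#' @keywords internal
validate_amino_profiles <- function(aa) {
  if (any(aa$value < 0))
    stop("negative amino-acid content at data row ",
         which(aa$value < 0)[1], call. = FALSE)
  bad_frac <- !aa$fraction %in% c("protein_bound", "free")
  if (any(bad_frac))
    stop("unknown fraction label: ", aa$fraction[which(bad_frac)[1]],
         call. = FALSE)
  bad_trt <- !aa$treatment %in% c("raw", "air", "microwave", "oil")
  if (any(bad_trt))
    stop("unknown treatment label: ", aa$treatment[which(bad_trt)[1]],
         call. = FALSE)
  destroyed <- aa$fraction == "protein_bound" &
    tolower(aa$residue) %in% c("trp", "tryptophan", "cys", "cysteine")
  if (any(destroyed))
    stop("tryptophan/cysteine cannot be measured in the protein-bound ",
         "fraction (destroyed by acid hydrolysis)", call. = FALSE)
  class(aa) <- c("amino_profile", "data.frame")
  aa
}

#' Write an amino-acid profile table to CSV
#' @param aa An `amino_profile` data frame.
#' @param path Output CSV path.
#' @export
write_amino_profiles <- function(aa, path) {
  utils::write.csv(as.data.frame(aa), path, row.names = FALSE)
  invisible(path)
}

#' Compose a hybrid genotype id from its parents
#'
#' Hybrid ids are `maternal x paternal` strings; reciprocal crosses are
#' distinct genotypes (they are grown and harvested separately).
#' @param maternal,paternal Parent inbred ids.
#' @return Character vector of hybrid ids.
#' @export
hybrid_id <- function(maternal, paternal) paste0(maternal, "x", paternal)
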