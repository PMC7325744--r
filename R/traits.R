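#' Canonical trait registry for popcorn hybrid trials
#'
#' Twelve traits are tracked in a standard pre-screening trial: germination
#' rate, days to pollination (DAP), rot/pest susceptibility, number of ears
#' harvested per row (NEH), ear length (EL), number of kernel rows per ear
#' (NRE), ear grain weight (EW), kernel size (KS), 100-grain weight,
#' vitreousness (1-7 light-box score), popability (PA) and expansion volume
#' (EV, mL popped flake per 20 g kernels).
#'
#' @format A data frame with one row per trait and columns `name`, `label`,
#'   `units`, `kind` (`proportion`, `count`, `score`, `continuous`).
#' @export
trait_registry <- function() {
  data.frame(
    name = c("germination", "dap", "rot", "neh", "el", "nre",
             "ew", "ks", "vit", "gw100", "pa", "ev"),
    label = c("Germination rate", "Days to pollination",
              "Rot/pest susceptibility", "Ears harvested per row",
              "Ear length", "Kernel rows per ear", "Ear grain weight",
              "Kernel size", "Vitreousness", "100-grain weight",
              "Popability", "Expansion volume"),
    units = c("proportion", "days", "proportion", "count", "cm", "count",
              "g", "kernels/10 g", "score 1-7", "g", "proportion",
              "mL/20 g"),
    kind = c("proportion", "continuous", "proportion", "count", "continuous",
             "count", "continuous", "count", "score", "continuous",
             "proportion", "continuous"),
    stringsAsFactors = FALSE
  )
}

#' Default selection-intensity weights and orientations
#'
#' The default economic weights grade traits for intermediate hybrid
#' selection on a 0-1 scale: popability and expansion volume 0.85, ear
#' weight 0.8, germination and 100-grain weight 0.7, vitreousness and ears
#' harvested 0.6, rot susceptibility and ear length 0.5, rows per ear 0.4.
#' Days to pollination and kernel size are recorded but excluded from
#' ranking (weight 0). Rot susceptibility is a "smaller is better" trait and
#' is complemented (x -> 1 - x) before ranking; all other weighted traits
#' are maximized directly.
#'
#' @return A `trait_spec` data frame with columns `name`, `orientation`
#'   (one of `maximize`, `complement_then_maximize`, `excluded`), `weight`
#'   and `units`.
#' @export
#' @examples
#' specs <- default_trait_specs()
#' specs[specs$name == "pa", "weight"]  # 0.85
default_trait_specs <- function() {
  reg <- trait_registry()
  weight <- c(germination = 0.7, dap = 0, rot = 0.5, neh = 0.6, el = 0.5,
              nre = 0.4, ew = 0.8, ks = 0, gw100 = 0.7, vit = 0.6,
              pa = 0.85, ev = 0.85)
  orientation <- ifelse(reg$name == "rot", "complement_then_maximize",
                        ifelse(weight[reg$name] == 0, "excluded", "maximize"))
  specs <- data.frame(
    name = reg$name,
    orientation = orientation,
    weight = unname(weight[reg$name]),
    units = reg$units,
    stringsAsFactors = FALSE
  )
  class(specs) <- c("trait_spec", "data.frame")
  validate_trait_specs(specs)
}

#' @keywords internal
validate_trait_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "orientation", "weight") %in% names(specs)))
  if (anyDuplicated(specs$name))
    stop("duplicate trait name in trait specs", call. = FALSE)
  bad <- !specs$orientation %in%
    c("maximize", "complement_then_maximize", "excluded")
  if (any(bad))
    stop("unknown orientation: ", paste(specs$orientation[bad], collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(specs$weight)) ||
      any(specs$weight < 0) || any(specs$weight > 1))
    stop("trait weights must lie in [0, 1]", call. = FALSE)
  # excluded <=> weight 0
  if (any((specs$weight == 0) != (specs$orientation == "excluded")))
    stop("a trait is excluded if and only if its weight is 0", call. = FALSE)
  specs
}

#' Load an analysis configuration
#'
#' Reads a YAML configuration with optional keys `traits:` (list of maps
#' with `name`, `weight`, and optionally `orientation`, `units`), `seed`,
#' `alpha`, `clip_negative_components`, and `ranking_variant`
#' (`"multiplicative"` or `"divisive"` placement of the sd homogeneity
#' term). Absent file or absent keys fall back to package defaults; trait
#' entries override the default weight table by name.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `qpp_config`: list with elements `traits`
#'   (a `trait_spec` data frame), `seed`, `alpha`,
#'   `clip_negative_components`, `ranking_variant`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$traits[cfg$traits$name == "ev", "weight"]  # 0.85
load_config <- function(path = NULL) {
  cfg <- list(
    traits = default_trait_specs(),
    seed = 20190101L,
    alpha = 0.05,
    clip_negative_components = TRUE,
    ranking_variant = "multiplicative"
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    for (key in c("seed", "alpha", "clip_negative_components",
                  "ranking_variant"))
      if (!is.null(raw[[key]])) cfg[[key]] <- raw[[key]]
    if (!is.null(raw$traits)) {
      for (tr in raw$traits) {
        if (is.null(tr$name)) stop("config trait entry lacks a name", call. = FALSE)
        i <- match(tr$name, cfg$traits$name)
        if (is.na(i)) {  # new trait declared by the user
          cfg$traits <- rbind(cfg$traits, data.frame(
            name = tr$name,
            orientation = if (is.null(tr$orientation)) "maximize" else tr$orientation,
            weight = if (is.null(tr$weight)) 0 else tr$weight,
            units = if (is.null(tr$units)) "" else tr$units,
            stringsAsFactors = FALSE))
        } else {
          if (!is.null(tr$weight)) cfg$traits$weight[i] <- tr$weight
          if (!is.null(tr$orientation)) cfg$traits$orientation[i] <- tr$orientation
          if (!is.null(tr$units)) cfg$traits$units[i] <- tr$units
        }
      }
      # keep the excluded <=> zero-weight invariant coherent after overrides
      cfg$traits$orientation[cfg$traits$weight == 0] <- "excluded"
      cfg$traits$orientation[cfg$traits$weight > 0 &
                             cfg$traits$orientation == "excluded"] <- "maximize"
      class(cfg$traits) <- c("trait_spec", "data.frame")
      validate_trait_specs(cfg$traits)
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  if (!cfg$ranking_variant %in% c("multiplicative", "divisive"))
    stop("ranking_variant must be 'multiplicative' or 'divisive'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "qpp_config")
}
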