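# Heavy-metal pollution indices: per-metal contamination factor (CF),
# multi-metal pollution load index (PLI) and pH-dependent Cd risk screening.

#' Contamination factor
#'
#' CF of a metal is the measured soil concentration divided by the regional
#' background concentration; CF > 1 means enrichment above background.
#'
#' @param concentration measured concentration, mg/kg (vectorised).
#' @param background regional background concentration, mg/kg (> 0).
#' @return dimensionless ratio `concentration / background`.
#' @examples
#' contamination_factor(35.81, 20.78)
#' @export
contamination_factor <- function(concentration, background) {
  if (any(background <= 0)) stop("background must be > 0", call. = FALSE)
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  concentration / background
}

#' Pollution load index
#'
#' The PLI over n metals is the geometric mean of their contamination
#' factors, \eqn{(\prod_i CF_i)^{1/n}}; a PLI above 1.0 indicates pollution.
#' Computed as `exp(mean(log(cf)))` for numerical stability.
#'
#' @param cfs numeric vector of contamination factors, all > 0.
#' @return dimensionless PLI.
#' @examples
#' pollution_load_index(c(4, 1, 1, 1))  # 4^(1/4)
#' @export
pollution_load_index <- function(cfs) {
  if (length(cfs) < 1) stop("need at least one CF", call. = FALSE)
  if (any(cfs <= 0))
    stop("all CFs must be > 0 (geometric mean undefined at 0)", call. = FALSE)
  exp(mean(log(cfs)))
}

#' pH-dependent cadmium risk screening
#'
#' Applies the paddy-soil Cd risk screening thresholds of GB 15618-2018:
#' 0.3 mg/kg for pH <= 5.5 and 0.4 mg/kg for 5.5 < pH <= 6.5. Above pH 6.5
#' a configurable threshold (default 0.6 mg/kg) is used and the result is
#' flagged as extrapolated. Exceedance is strict (`total_cd > threshold`).
#'
#' @param ph soil pH in (0, 14) (vectorised with `total_cd`).
#' @param total_cd total Cd concentration, mg/kg.
#' @param high_ph_threshold threshold applied when pH > 6.5.
#' @return logical vector of exceedances, with attributes `threshold`
#'   (mg/kg applied per sample) and `extrapolated` (TRUE where pH > 6.5).
#' @examples
#' cd_risk_screen(c(4.97, 5.5), c(1.62, 0.3))
#' @export
cd_risk_screen <- function(ph, total_cd, high_ph_threshold = 0.6) {
  if (any(ph <= 0 | ph >= 14)) stop("pH must be in (0, 14)", call. = FALSE)
  thr <- ifelse(ph <= 5.5, 0.3, ifelse(ph <= 6.5, 0.4, high_ph_threshold))
  out <- total_cd > thr
  attr(out, "threshold") <- thr
  attr(out, "extrapolated") <- ph > 6.5
  out
}

#' Assess pollution at one site
#'
#' Computes the per-metal CF (on total concentrations), the PLI over the
#' four core metals Cd, Cu, Pb and Zn, the pollution flag (PLI > 1.0) and
#' the Cd screening exceedance for a single sample.
#'
#' @param metals one-row slice of a [read_metal_table] result (or any list
#'   with `total_<Metal>` entries and a `sample_id`).
#' @param backgrounds named numeric vector of background concentrations
#'   covering every metal assessed.
#' @param ph soil pH of the sample.
#' @return list with `sample_id`, `cf` (named numeric), `pli`, `polluted`,
#'   `cd_exceeds_screen`.
#' @export
assess_site <- function(metals, backgrounds, ph) {
  present <- sub("^total_", "", grep("^total_", names(metals), value = TRUE))
  missing_bg <- setdiff(present, names(backgrounds))
  if (length(missing_bg))
    stop("no background for metal(s): ", paste(missing_bg, collapse = ", "),
         call. = FALSE)
  cf <- vapply(present, function(me)
    contamination_factor(as.numeric(metals[[paste0("total_", me)]]),
                         backgrounds[[me]]), numeric(1))
  core <- c("Cd", "Cu", "Pb", "Zn")
  pli <- pollution_load_index(cf[core])
  list(sample_id = as.character(metals[["sample_id"]]),
       cf = cf, pli = pli, polluted = pli > 1.0,
       cd_exceeds_screen = as.logical(
         cd_risk_screen(ph, as.numeric(metals[["total_Cd"]]))))
}

#' Assess pollution for every sample of a metal table
#'
#' @param metals a [read_metal_table] result.
#' @param backgrounds named numeric vector of backgrounds.
#' @param soil optional [read_soil_table] result supplying per-sample pH
#'   (matched by `sample_id`) for the Cd screen; without it the screen
#'   column is `NA`.
#' @return data frame with one row per sample: `sample_id`, `CF_<Metal>`
#'   columns, `PLI`, `polluted`, `cd_exceeds_screen`.
#' @examples
#' fx <- paper_fixture()
#' head(assess_pollution(fx$metals, fx$backgrounds, fx$soil))
#' @export
assess_pollution <- function(metals, backgrounds, soil = NULL) {
  ph <- rep(NA_real_, nrow(metals))
  if (!is.null(soil)) {
    ph <- soil$ph[match(metals$sample_id, soil$sample_id)]
    if (anyNA(ph))
      warning("no pH for sample(s): ",
              paste(metals$sample_id[is.na(ph)], collapse = ", "),
              "; Cd screen set to NA", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(metals)), function(i) {
    res <- assess_site(metals[i, , drop = FALSE], backgrounds,
                       ph = if (is.na(ph[i])) 7 else ph[i])
    if (is.na(ph[i])) res$cd_exceeds_screen <- NA
    cfs <- as.list(res$cf); names(cfs) <- paste0("CF_", names(res$cf))
    as.data.frame(c(list(sample_id = res$sample_id), cfs,
                    list(PLI = res$pli, polluted = res$polluted,
                         cd_exceeds_screen = res$cd_exceeds_screen)),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
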