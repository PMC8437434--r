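#' Fluorescence anisotropy titration
#'
#' @param ligand_conc Titrant concentrations, uM, non-negative and
#'   increasing; at least 6 points.
#' @param anisotropy Steady-state anisotropy values.
#' @param labeled_conc Concentration of the fluorescently labeled species,
#'   uM (fixed; 0.1 uM in the assay design).
#' @return A `titration_curve` object.
#' @export
titration_curve <- function(ligand_conc, anisotropy, labeled_conc = 0.1) {
  ligand_conc <- as.numeric(ligand_conc)
  anisotropy <- as.numeric(anisotropy)
  if (length(ligand_conc) != length(anisotropy) || length(ligand_conc) < 6L)
    stop("need >= 6 titration points", call. = FALSE)
  if (any(ligand_conc < 0)) stop("ligand concentrations must be >= 0",
                                 call. = FALSE)
  if (is.unsorted(ligand_conc))
    stop("ligand concentrations must be increasing", call. = FALSE)
  structure(list(ligand_conc = ligand_conc, anisotropy = anisotropy,
                 labeled_conc = labeled_conc),
            class = "titration_curve")
}

#' One-site binding fit of an anisotropy titration
#'
#' Fits `r(c) = r_free + (r_bound - r_free) * c / (KD + c)`. The hyperbolic
#' form neglects ligand depletion, justified because the labeled species
#' (0.1 uM) is far below every KD of interest; set `quadratic = TRUE` for the
#' exact one-site solution that accounts for depletion. A fit is declared
#' unidentifiable (no binding, the DNAJB1-monomer case) when the fitted
#' amplitude is smaller than 3 times the residual noise.
#'
#' @param curve [titration_curve()].
#' @param quadratic Use the exact (ligand-depletion) form.
#' @return List with `KD` (uM, `NA` when unidentifiable), `KD_stderr`,
#'   `r_free`, `r_bound`, `identifiable`, `rmse`.
#' @examples
#' cc <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
#' r <- 0.05 + 0.15 * cc / (7.6 + cc)
#' fit_one_site(titration_curve(cc, r))$KD
#' @export
fit_one_site <- function(curve, quadratic = FALSE) {
  stopifnot(inherits(curve, "titration_curve"))
  c_ <- curve$ligand_conc
  r <- curve$anisotropy
  r_free0 <- r[1]
  r_bound0 <- r[length(r)]
  amp0 <- r_bound0 - r_free0
  KD0 <- max(c_[c_ > 0][1], stats::median(c_))
  model <- if (quadratic) {
    lt <- curve$labeled_conc
    function(cc, KD, rf, rb) {
      s <- lt + cc + KD
      fb <- (s - sqrt(s^2 - 4 * lt * cc)) / (2 * lt)
      rf + (rb - rf) * fb
    }
  } else {
    function(cc, KD, rf, rb) rf + (rb - rf) * cc / (KD + cc)
  }
  fit <- try(stats::nls(r ~ model(c_, KD, rf, rb),
                        start = list(KD = KD0, rf = r_free0, rb = r_bound0),
                        control = stats::nls.control(maxiter = 500,
                                                     scaleOffset = 1,
                                                     warnOnly = TRUE),
                        lower = c(KD = 1e-6, rf = -Inf, rb = -Inf),
                        algorithm = "port"),
             silent = TRUE)
  flat <- list(KD = NA_real_, KD_stderr = NA_real_, r_free = mean(r),
               r_bound = mean(r), identifiable = FALSE,
               rmse = stats::sd(r))
  if (inherits(fit, "try-error")) return(flat)
  cf <- stats::coef(fit)
  res_sd <- sqrt(sum(stats::resid(fit)^2) / max(1, length(r) - 3))
  amp <- cf[["rb"]] - cf[["rf"]]
  if (abs(amp) < 3 * res_sd) {
    flat$rmse <- sqrt(mean(stats::resid(fit)^2))
    return(flat)
  }
  se <- tryCatch(stats::coef(summary(fit))["KD", "Std. Error"],
                 error = function(e) NA_real_)
  list(KD = unname(cf[["KD"]]), KD_stderr = unname(se),
       r_free = unname(cf[["rf"]]), r_bound = unname(cf[["rb"]]),
       identifiable = TRUE, rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Per-residue NMR peak table
#'
#' @param residue Integer sequence positions (unique).
#' @param delta_H Amide 1H chemical shift differences, ppm.
#' @param delta_N 15N chemical shift differences, ppm.
#' @param I Bound-state peak intensities (volumes), a.u.
#' @param I0 Free-state peak intensities, a.u.
#' @return data.frame of class `peak_table`.
#' @export
peak_table <- function(residue, delta_H = NA_real_, delta_N = NA_real_,
                       I = NA_real_, I0 = NA_real_) {
  residue <- as.integer(residue)
  if (anyDuplicated(residue)) stop("residues must be unique", call. = FALSE)
  df <- data.frame(residue = residue, delta_H = delta_H, delta_N = delta_N,
                   I = I, I0 = I0)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Combined chemical shift perturbations
#'
#' `delta = sqrt(delta_H^2 + (delta_N / 5)^2)` per residue; the nitrogen
#' shift is scaled by 5 to account for its wider dispersion. Residues with a
#' missing shift pair are skipped with a message.
#'
#' @param records A [peak_table()].
#' @return data.frame with columns `residue`, `csp` (ppm).
#' @export
compute_csp <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("residue", "delta_H", "delta_N") %in% names(records)))
  ok <- is.finite(records$delta_H) & is.finite(records$delta_N)
  if (any(!ok))
    message(sum(!ok), " residue(s) skipped: missing shift pair")
  data.frame(residue = records$residue[ok],
             csp = sqrt(records$delta_H[ok]^2 + (records$delta_N[ok] / 5)^2))
}

#' Flag significant chemical shift perturbations
#'
#' A residue is significant when its CSP exceeds the mean plus one standard
#' deviation of all quantified residues (binding region included).
#'
#' @param csps data.frame from [compute_csp()] (columns `residue`, `csp`).
#' @return Logical vector aligned with `csps$residue`.
#' @export
flag_significant_csp <- function(csps) {
  stopifnot(is.data.frame(csps), "csp" %in% names(csps))
  if (nrow(csps) < 5L) stop("need >= 5 residues", call. = FALSE)
  thr <- mean(csps$csp) + stats::sd(csps$csp)
  if (!is.finite(thr) || stats::sd(csps$csp) == 0)
    return(rep(FALSE, nrow(csps)))
  csps$csp > thr
}

#' Intensity-ratio binding profile
#'
#' Computes `I/I0` per residue. Residues whose ratio falls more than one
#' standard deviation below the mean ratio are significant (binding); ratios
#' below 0.5 additionally carry a strong-attenuation flag indicating
#' intermolecular interaction.
#'
#' @param records A [peak_table()] with `I` and `I0`.
#' @param strong_cutoff Strong-attenuation threshold on the ratio.
#' @return data.frame of class `binding_profile` with columns `residue`,
#'   `ratio`, `significant`, `strong`.
#' @export
intensity_ratio_profile <- function(records, strong_cutoff = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("residue", "I", "I0") %in% names(records)))
  ok <- is.finite(records$I) & is.finite(records$I0) & records$I0 != 0
  if (any(is.finite(records$I0) & records$I0 == 0))
    warning("residue(s) with I0 = 0 excluded", call. = FALSE)
  ratio <- records$I[ok] / records$I0[ok]
  if (any(ratio < 0)) stop("negative intensity ratio", call. = FALSE)
  thr <- mean(ratio) - stats::sd(ratio)
  sig <- if (is.finite(thr) && stats::sd(ratio) > 0) ratio < thr
         else rep(FALSE, length(ratio))
  out <- data.frame(residue = records$residue[ok], ratio = ratio,
                    significant = sig, strong = ratio < strong_cutoff)
  class(out) <- c("binding_profile", "data.frame")
  out
}

#' Call contiguous binding regions from a profile
#'
#' Maximal runs of at least `min_run` consecutive significant residues are
#' reported as closed intervals; single-residue gaps inside a run are bridged
#' when `bridge_gaps = TRUE`.
#'
#' @param profile [intensity_ratio_profile()] output, or any data.frame with
#'   `residue` and `significant` columns.
#' @param min_run Minimum run length (default 3).
#' @param bridge_gaps Bridge single-residue gaps.
#' @return data.frame with columns `start`, `end` (residue numbers); zero
#'   rows when nothing is significant.
#' @export
call_binding_regions <- function(profile, min_run = 3L, bridge_gaps = TRUE) {
  stopifnot(is.data.frame(profile),
            all(c("residue", "significant") %in% names(profile)),
            min_run >= 1)
  df <- profile[order(profile$residue), ]
  sig_res <- df$residue[df$significant]
  empty <- data.frame(start = integer(0), end = integer(0))
  if (length(sig_res) == 0L) return(empty)
  if (bridge_gaps) {
    # a residue closing a single-residue gap between two significant ones
    gapfill <- df$residue[!df$significant &
                            (df$residue - 1) %in% sig_res &
                            (df$residue + 1) %in% sig_res]
    sig_res <- sort(c(sig_res, gapfill))
  }
  breaks <- which(diff(sig_res) > 1)
  starts <- sig_res[c(1, breaks + 1)]
  ends <- sig_res[c(breaks, length(sig_res))]
  keep <- (ends - starts + 1) >= min_run
  if (!any(keep)) return(empty)
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}
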