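#' Kinetic dataset: a collection of traces grouped by condition
#'
#' @param traces List of [mass_trace()] (or [raw_trace()]) objects.
#' @param replicate_sets Optional partition labels (one per trace) used for
#'   replicate-set error estimation.
#' @return A `kinetic_dataset` object.
#' @export
kinetic_dataset <- function(traces, replicate_sets = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  ok <- vapply(traces, function(x)
    inherits(x, "mass_trace") || inherits(x, "raw_trace"), TRUE)
  if (!all(ok)) stop("traces must be raw_trace or mass_trace objects",
                     call. = FALSE)
  if (!is.null(replicate_sets) && length(replicate_sets) != length(traces))
    stop("replicate_sets must label every trace", call. = FALSE)
  structure(list(traces = traces, replicate_sets = replicate_sets),
            class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  m0s <- vapply(x$traces, function(tr) tr$condition$m0, numeric(1))
  seeded <- vapply(x$traces, function(tr) tr$condition$seeded, TRUE)
  chap <- vapply(x$traces, function(tr) tr$condition$chaperone, "")
  cat(sprintf("Kinetic dataset: %d traces; m0 in [%g, %g] uM; %d seeded; chaperones: %s\n",
              length(x$traces), min(m0s), max(m0s), sum(seeded),
              paste(unique(chap), collapse = ", ")))
  invisible(x)
}

#' Filter a kinetic dataset by condition
#'
#' @param dataset A [kinetic_dataset()].
#' @param chaperone,seeded,chaperone_conc Optional filters; `NULL` keeps all.
#' @return A [kinetic_dataset()] with the matching traces.
#' @export
filter_dataset <- function(dataset, chaperone = NULL, seeded = NULL,
                           chaperone_conc = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  keep <- rep(TRUE, length(dataset$traces))
  cond <- lapply(dataset$traces, `[[`, "condition")
  if (!is.null(chaperone))
    keep <- keep & vapply(cond, `[[`, "", "chaperone") %in% chaperone
  if (!is.null(seeded))
    keep <- keep & vapply(cond, `[[`, TRUE, "seeded") == seeded
  if (!is.null(chaperone_conc))
    keep <- keep & vapply(cond, `[[`, 0, "chaperone_conc") %in% chaperone_conc
  if (!any(keep)) stop("no traces match the filter", call. = FALSE)
  kinetic_dataset(dataset$traces[keep],
                  if (is.null(dataset$replicate_sets)) NULL
                  else dataset$replicate_sets[keep])
}

.condition_to_row <- function(cond) {
  data.frame(m0_uM = cond$m0, chaperone = cond$chaperone,
             chaperone_uM = cond$chaperone_conc, seeded = cond$seeded,
             seed_mass_uM = cond$seed_mass,
             replicate = as.character(cond$replicate),
             stringsAsFactors = FALSE)
}

#' Write traces to a long-format CSV
#'
#' Raw traces use columns `time_min, signal_au, well, m0_uM, chaperone,
#' chaperone_uM, seeded, seed_mass_uM, replicate`; mass traces replace
#' `signal_au` with `M_uM`.
#'
#' @param traces List of [raw_trace()] or [mass_trace()] objects (one kind).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(length(traces) >= 1L)
  is_raw <- inherits(traces[[1]], "raw_trace")
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    meta <- .condition_to_row(tr$condition)
    vals <- if (is_raw) tr$signal else tr$M
    df <- data.frame(time_min = tr$times, value = vals, well = i)
    names(df)[2] <- if (is_raw) "signal_au" else "M_uM"
    cbind(df, meta[rep(1, nrow(df)), , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from a long-format CSV
#'
#' Inverse of [write_traces_csv()]: traces are split by the `well` column and
#' rebuilt with their condition metadata.
#'
#' @param path CSV path.
#' @return List of [raw_trace()] or [mass_trace()] objects, according to
#'   whether the file carries `signal_au` or `M_uM`.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_raw <- "signal_au" %in% names(df)
  vcol <- if (is_raw) "signal_au" else "M_uM"
  if (!vcol %in% names(df))
    stop("CSV must contain a signal_au or M_uM column", call. = FALSE)
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    cond <- trace_condition(m0 = d$m0_uM[1], chaperone = d$chaperone[1],
                            chaperone_conc = d$chaperone_uM[1],
                            seeded = as.logical(d$seeded[1]),
                            seed_mass = d$seed_mass_uM[1],
                            replicate = d$replicate[1])
    if (is_raw) raw_trace(d$time_min, d$signal_au, cond)
    else mass_trace(d$time_min, d$M_uM, cond)
  })
}
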