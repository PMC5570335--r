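# Trace file I/O and ASL signal-to-perfusion conversion.

#' Convert an ASL difference signal to perfusion
#'
#' `f = lambda * dM / (2 * TI1 * M0b * exp(-PLD / T1b))`, reported in
#' mL/100g/min (the partition coefficient `lambda` is in mL/g and `TI1` in
#' seconds, so the raw quotient is per gram per second and is scaled by
#' 6000).
#'
#' @param dM ASL difference-signal series (arbitrary units).
#' @param M0b Signal of fully relaxed blood, same units as `dM`; must be
#'   positive.
#' @param constants An [rh_constants()] list (supplies `TI1`, `PLD`,
#'   `lambda`, `T1b`).
#' @return Perfusion series, mL/100g/min.
#' @seealso [rh_perfusion_to_signal()] for the exact inverse.
#' @export
rh_signal_to_perfusion <- function(dM, M0b, constants = rh_constants()) {
  if (!is.numeric(M0b) || length(M0b) != 1 || M0b <= 0)
    stop("M0b must be a positive scalar")
  cst <- constants
  6000 * cst$lambda * dM / (2 * cst$TI1 * M0b * exp(-cst$PLD / cst$T1b))
}

#' @rdname rh_signal_to_perfusion
#' @param f Perfusion series, mL/100g/min.
#' @export
rh_perfusion_to_signal <- function(f, M0b, constants = rh_constants()) {
  if (!is.numeric(M0b) || length(M0b) != 1 || M0b <= 0)
    stop("M0b must be a positive scalar")
  cst <- constants
  f * (2 * cst$TI1 * M0b * exp(-cst$PLD / cst$T1b)) / (6000 * cst$lambda)
}

#' Write / read a perfusion trace as annotated CSV
#'
#' The file carries the protocol in `#`-prefixed header lines followed by a
#' CSV body with columns `time_s`, `perfusion`, `phase`, so a write/read
#' round trip is lossless.
#'
#' @param trace A trace tibble with a protocol attribute.
#' @param path File path.
#' @return `rh_write_trace()` returns `path` invisibly; `rh_read_trace()`
#'   returns the trace tibble with its protocol attribute restored.
#' @export
rh_write_trace <- function(trace, path) {
  need <- c("time_s", "perfusion", "phase")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace lacks column(s): ", paste(miss, collapse = ", "))
  prot <- .trace_protocol(trace)
  meta <- attr(trace, "meta")
  hdr <- c("# rhasl_trace v1",
           sprintf("# t_cuff: %.6g", prot$t_cuff),
           sprintf("# t_baseline: %.6g", prot$t_baseline),
           sprintf("# t_recovery: %.6g", prot$t_recovery),
           sprintf("# dt_sample: %.6g", prot$dt_sample),
           if (!is.null(meta$label)) sprintf("# label: %s", meta$label))
  body <- readr::format_csv(trace[, need])
  writeLines(c(hdr, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname rh_write_trace
#' @export
rh_read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getnum <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  tr <- readr::read_csv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE)
  need <- c("time_s", "perfusion", "phase")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(tr$time_s)) || is.unsorted(tr$time_s, strictly = TRUE))
    stop("parse error in ", path, ": time_s must be strictly increasing")
  tc <- getnum("t_cuff"); tb <- getnum("t_baseline")
  trec <- getnum("t_recovery"); dt <- getnum("dt_sample")
  if (is.null(tc))
    stop("parse error in ", path, ": header lacks '# t_cuff:'")
  attr(tr, "protocol") <- rh_protocol(
    t_cuff = tc,
    t_baseline = if (is.null(tb)) -min(tr$time_s) else tb,
    t_recovery = if (is.null(trec)) max(tr$time_s) - tc else trec,
    dt_sample = if (is.null(dt)) stats::median(diff(tr$time_s)) else dt)
  lab <- grep("^# label:", hdr, value = TRUE)
  if (length(lab))
    attr(tr, "meta") <- list(label = sub("^# label:\\s*", "", lab[1]))
  tr
}
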