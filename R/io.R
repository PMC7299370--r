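#' Write a sweep set to a wide CSV with a sidecar config
#'
#' Column 1 is `time_ms`; columns 2..M+1 are `sweep_0001`... in pA. The
#' protocol metadata (holding potential, dt, windows, seed, condition) is
#' written to a key-value sidecar file `<path minus .csv>.cfg` so that
#' [read_sweeps()] can rebuild the full object.
#'
#' @param x a [sweep_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(x, path) {
  df <- data.frame(time_ms = x$time_ms, x$sweeps, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- c(
    v_hold = x$v_hold, dt = x$dt,
    t0_agonist = x$t0_agonist, pulse_dur = x$pulse_dur,
    baseline_start = x$baseline_window[1], baseline_end = x$baseline_window[2],
    analysis_start = x$analysis_window[1], analysis_end = x$analysis_window[2],
    seed = x$seed
  )
  lines <- sprintf("%s = %s", names(cfg), format(cfg, digits = 15, trim = TRUE))
  for (nm in names(x$labels))
    lines <- c(lines, sprintf("%s = %s", nm, x$labels[[nm]]))
  writeLines(lines, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".cfg")

# Parse a "key = value" text file into a named character vector.
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)\\s*$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  stats::setNames(vapply(kv, `[`, character(1), 3),
                  vapply(kv, `[`, character(1), 2))
}

#' Read a sweep set from the wide CSV dialect
#'
#' Inverse of [write_sweeps()]; `read(write(x))` reproduces `x` up to float
#' formatting. Ragged rows and non-monotone time are explicit parse errors.
#'
#' @param path CSV path (sidecar `.cfg` expected next to it).
#' @return a [sweep_set()].
#' @export
read_sweeps <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (names(df)[1] != "time_ms") stop("first column must be time_ms")
  tm <- df[[1]]
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("non-monotone time column at row ", bad[1] + 1)
  cfg <- read_config(sidecar_path(path))
  num <- function(key, default = NA_real_) {
    if (key %in% names(cfg)) as.numeric(cfg[[key]]) else default
  }
  known <- c("v_hold", "dt", "t0_agonist", "pulse_dur", "baseline_start",
             "baseline_end", "analysis_start", "analysis_end", "seed")
  labels <- as.list(cfg[setdiff(names(cfg), known)])
  sweep_set(
    tm, as.matrix(df[, -1, drop = FALSE]),
    v_hold = num("v_hold"),
    t0_agonist = num("t0_agonist"), pulse_dur = num("pulse_dur"),
    baseline_window = c(num("baseline_start"), num("baseline_end")),
    analysis_window = c(num("analysis_start"), num("analysis_end")),
    labels = labels, seed = as.integer(num("seed"))
  )
}
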