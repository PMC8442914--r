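#' Default run configuration
#'
#' The headline parameter setting used throughout: `A = 13.0, B = 5.821,
#' w1 = 0.2223, w2 = 1.487, K = 0.9` for the map, `C = 0.2, x_d = 0,
#' sigma = 1.0, D = 0, alpha = 0.15, p = 32` for the control, and ten
#' trials of 1000 transient + 20000 recorded steps, seed 1, for the
#' simulation.
#'
#' @return A list of class `"rro_config"` with elements `model`, `control`,
#'   `sim`.
#' @export
default_config <- function() {
  structure(list(model = model_params(), control = control_params(),
                 sim = sim_config()),
            class = "rro_config")
}

# Known config keys per section, mapped onto constructor arguments.
config_keys <- list(
  model = c("A", "B", "w1", "w2", "K"),
  control = c("C", "x_d", "sigma", "D", "alpha", "p"),
  sim = c("n_transient", "n_samples", "n_trials", "seed", "x0")
)

#' Load a run configuration from a structured text file
#'
#' Parses an INI-style file with sections `[model]`, `[control]`, `[sim]`
#' and `key = value` lines (`#` or `;` comments allowed).  Unset fields keep
#' the [default_config()] values; unknown sections or keys are rejected
#' with an error naming the offender, and range violations are reported by
#' the parameter constructors (naming the field).
#'
#' @param path Path to the config file.
#' @return A list of class `"rro_config"` with `model`, `control`, `sim`.
#' @examples
#' f <- tempfile(fileext = ".ini")
#' writeLines(c("[model]", "K = 0.91", "[control]", "C = 0.3"), f)
#' load_config(f)$model$K
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list(model = list(), control = list(), sim = list())
  section <- NA_character_
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(config_keys))
        stop("unknown config section: [", section, "]", call. = FALSE)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse config line: \"", ln, "\"", call. = FALSE)
    if (is.na(section))
      stop("key outside any [section]: \"", ln, "\"", call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (!key %in% config_keys[[section]])
      stop("unknown key '", key, "' in section [", section, "]",
           call. = FALSE)
    val <- suppressWarnings(as.numeric(trimws(paste(kv[-1], collapse = "="))))
    if (is.na(val))
      stop("non-numeric value for '", key, "'", call. = FALSE)
    vals[[section]][[key]] <- val
  }
  structure(list(model = do.call(model_params, vals$model),
                 control = do.call(control_params, vals$control),
                 sim = do.call(sim_config, vals$sim)),
            class = "rro_config")
}

#' @export
print.rro_config <- function(x, ...) {
  print(x$model); print(x$control); print(x$sim)
  invisible(x)
}

#' Write a result table as self-describing TSV
#'
#' Serializes a sweep table or trajectory to tab-separated text with a
#' `#`-prefixed header block recording every generating parameter (taken
#' from the object's `params` attribute, including the master seed), then
#' a column-name row and the data.  Numbers are written with 10 significant
#' digits, so [read_table()] round-trips losslessly at that precision.
#'
#' @param table A data frame (e.g. an [iterate()] trajectory or a sweep
#'   table); for a [sweep_bifurcation()] result pass `$metrics` or
#'   `$samples`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  if (inherits(table, "bifurcation_sweep"))
    stop("write the $metrics or $samples component of a bifurcation sweep",
         call. = FALSE)
  stopifnot(is.data.frame(table))
  pars <- attr(table, "params")
  if (is.null(pars) && inherits(table, "rro_trajectory")) {
    mp <- attr(table, "model"); cp <- attr(table, "control")
    sc <- attr(table, "sim")
    pars <- sweep_params(mp, cp, sc)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(pars))
    writeLines(sprintf("# %s: %s", nm, format(pars[[nm]], digits = 10)), con)
  fmt <- vapply(table, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col)
    else as.character(col)
  }, character(nrow(table)))
  if (nrow(table) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(paste(names(table), collapse = "\t"), con)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a TSV file with a `#` header block.
#' @return A data frame; the parsed header key-value pairs are attached as
#'   attribute `"params"`.
#' @export
read_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  pars <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    pars[[key]] <- if (is.na(num)) val else num
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "params") <- pars
  df
}
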