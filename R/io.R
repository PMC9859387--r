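#' Load a full run configuration
#'
#' Reads a flat YAML run configuration and applies defaults that reproduce
#' the canonical setup: default parameters, `method = "rk4"`, `dt = 1`,
#' `t_end = 20`, `anchor = "printed_t5"` (the year-five fixture state),
#' `seed = 1`. Unknown keys are rejected with the offending key named;
#' every applied default is reported via `message()`.
#'
#' Recognised keys: `parameters` (a block with any of `lambda`, `delta`,
#' `mu`, `gamma`, `nu`, `incidence`), `method`, `dt`, `t_end`, `anchor`
#' (`"printed_t5"`, `"equilibrium_offset"`, or a block with `t`, `C`, `N`),
#' `out_dir`, `seed`, `rounding` (`"full"` or `"printed"`).
#'
#' @param path path to the YAML file; an empty file yields the full
#'   defaults.
#' @param quiet suppress the applied-defaults messages.
#' @return list of class `dc_config` with fields `params` (a
#'   [dc_params()]), `method`, `dt`, `t_end`, `anchor`, `out_dir`, `seed`,
#'   `rounding`.
#' @export
dc_read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "cannot parse config '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (is.null(raw)) raw <- list()
  allowed <- c("parameters", "method", "dt", "t_end", "anchor", "out_dir",
               "seed", "rounding")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- list(method = "rk4", dt = 1, t_end = 20, anchor = "printed_t5",
                   out_dir = ".", seed = 1L, rounding = "full")
  applied <- setdiff(names(defaults), names(raw))
  if (!quiet && length(applied) > 0) {
    message("config defaults applied: ", paste(applied, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), "parameters")])
  if (is.list(cfg$anchor)) {
    # YAML 1.1 reads a bare `N` key as boolean FALSE; restore it
    names(cfg$anchor)[names(cfg$anchor) == "FALSE"] <- "N"
  }
  par_block <- if (is.null(raw$parameters)) list() else raw$parameters
  par_allowed <- c("lambda", "delta", "mu", "gamma", "nu", "incidence")
  par_unknown <- setdiff(names(par_block), par_allowed)
  if (length(par_unknown) > 0) {
    stop(sprintf("unknown parameter key(s): %s",
                 paste(par_unknown, collapse = ", ")), call. = FALSE)
  }
  par_full <- utils::modifyList(unclass(dc_default_params()), par_block)
  cfg$params <- tryCatch(do.call(dc_params, par_full),
                         error = function(e) stop(sprintf(
                           "invalid parameters block: %s", conditionMessage(e)),
                           call. = FALSE))
  cfg$method <- match.arg(cfg$method,
                          c("explicit_euler", "implicit_euler", "heun",
                            "rk4", "abm4", "analytic"))
  cfg$rounding <- match.arg(cfg$rounding, c("full", "printed"))
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) stop("config key 'dt' must be > 0",
                                               call. = FALSE)
  if (!is.numeric(cfg$t_end) || cfg$t_end <= 0) stop(
    "config key 't_end' must be > 0", call. = FALSE)
  structure(cfg[c("params", "method", "dt", "t_end", "anchor", "out_dir",
                  "seed", "rounding")], class = "dc_config")
}

#' Resolve the anchor choice of a configuration into a state
#'
#' @param config a [dc_read_config()] object.
#' @return a [dc_state()].
#' @export
dc_resolve_anchor <- function(config) {
  a <- config$anchor
  if (identical(a, "printed_t5")) {
    dc_anchor_fixture()$anchor
  } else if (identical(a, "equilibrium_offset")) {
    dc_initial_state(config$params, 500, 500)
  } else if (is.list(a) && all(c("t", "C", "N") %in% names(a))) {
    dc_state(a$t, a$C, a$N)
  } else {
    stop("config key 'anchor' must be 'printed_t5', 'equilibrium_offset', or a t/C/N block",
         call. = FALSE)
  }
}

.dc_write_csv <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' Write an error table as CSV
#'
#' Writes the table at full double precision, and with
#' `printed_variant = TRUE` also writes a companion `*_printed.csv` with
#' persons rounded to 2 decimals and errors to 4 significant figures —
#' the print style of the reference tables.
#'
#' @param table a [dc_error_table()] data.frame.
#' @param path output CSV path.
#' @param printed_variant also write the rounded companion file.
#' @return `path`, invisibly.
#' @export
dc_write_error_table <- function(table, path, printed_variant = TRUE) {
  full <- as.data.frame(table)
  .dc_write_csv(format(full, digits = 17, scientific = FALSE, trim = TRUE),
                path)
  if (printed_variant) {
    pr <- full
    for (col in c("C_num", "C_true", "N_num", "N_true")) {
      pr[[col]] <- sprintf("%.2f", full[[col]])
    }
    for (col in c("err_C_pct", "err_N_pct")) {
      pr[[col]] <- paste0(vapply(full[[col]], .dc_fmt_pct, character(1)), "%")
    }
    .dc_write_csv(pr, sub("\\.csv$", "_printed.csv", path))
  }
  invisible(path)
}

# 4 significant figures as plain decimals, at least 4 decimal places
# (reference-table style: 0.0171, 0.00000014, 0.0000 for a value below the
# finest precision the tables print)
.dc_fmt_pct <- function(x) {
  if (!is.finite(x) || abs(x) < 1e-10) return(formatC(0, format = "f", digits = 4))
  dec <- max(4L, 3L - floor(log10(abs(x))))
  formatC(signif(x, 4), format = "f", digits = dec)
}

#' Write a trajectory as CSV
#'
#' Columns `t`, `C`, `N`, `D`, `method`, `dt`, written at full precision;
#' a read-back with `read.csv` reproduces the in-memory values bitwise.
#'
#' @param traj a `dc_trajectory` from [dc_integrate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
dc_write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$method <- attr(traj, "method")
  df$dt <- attr(traj, "dt")
  out <- df
  for (col in c("t", "C", "N", "D", "dt")) {
    out[[col]] <- sprintf("%.17g", df[[col]])
  }
  .dc_write_csv(out, path)
}
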