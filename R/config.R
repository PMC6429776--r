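# Run configuration: term toggles, solvent model, minimizer settings.
# Mirrors a key=value config file with '#' comments.

#' Default run configuration
#'
#' @return Named list of configuration values:
#' \describe{
#'   \item{electrostatics, vdw}{"on"/"off" switches for the point-charge
#'     and Lennard-Jones terms.}
#'   \item{solvent}{"gb" (generalized Born, pairwise-descreening variant)
#'     or "vacuum".}
#'   \item{hbonds, planarity, backbone_regularization, springs}{switches
#'     for the four add-on restraint terms; with all four off the energy is
#'     the plain force field.}
#'   \item{cutoff}{Non-bonded cutoff in Angstrom, or "none" (the system is
#'     non-periodic; no cutoff by default).}
#'   \item{scale_14_elec, scale_14_lj}{1-4 scaling factors (AMBER
#'     convention 1/1.2 and 1/2).}
#'   \item{algorithm}{"prcg" (Polak-Ribiere conjugate gradients) or "sd"
#'     (steepest descent).}
#'   \item{max_steps}{Minimization step budget (default 10000).}
#'   \item{grad_tol}{Gradient-norm convergence threshold, kcal/mol/A.}
#'   \item{gs_tol}{Golden-section line-search tolerance, Angstrom.}
#'   \item{bracket_growth}{Geometric growth factor of the line-search
#'     bracket.}
#' }
#' @export
default_config <- function() {
  list(electrostatics = "on", vdw = "on", solvent = "gb",
       hbonds = "on", planarity = "on", backbone_regularization = "on",
       springs = "on", cutoff = "none",
       scale_14_elec = 1 / 1.2, scale_14_lj = 0.5,
       epsilon_in = 1.0, epsilon_out = 78.5,
       algorithm = "prcg", max_steps = 10000L, grad_tol = 0.05,
       gs_tol = 1e-4, bracket_growth = 2.0, ls_cap = 1.0,
       log_interval = 50L)
}

#' Parse a key=value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment.
#' Unknown keys are an error. Values are merged over
#' \code{\link{default_config}}.
#'
#' @param text Config text (string, vector of lines, or a file path).
#' @return Full configuration list.
#' @export
parse_config <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
               file.exists(text)) readLines(text, warn = FALSE)
           else if (length(text) == 1L) strsplit(text, "\n",
                                                 fixed = TRUE)[[1]]
           else text
  cfg <- default_config()
  lines <- sub("#.*$", "", lines)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (!grepl("=", line, fixed = TRUE))
      stop("config line ", i, ": expected key=value", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg))
      stop("config line ", i, ": unknown key '", key, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num) && !key %in%
                      c("electrostatics", "vdw", "solvent", "hbonds",
                        "planarity", "backbone_regularization", "springs",
                        "algorithm")) num else val
  }
  cfg
}

merge_config <- function(...) {
  cfg <- default_config()
  for (over in list(...)) {
    if (is.null(over)) next
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg
}

cfg_on <- function(cfg, key) identical(cfg[[key]], "on")
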