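# Top-level refinement interface: read -> normalize/protonate -> topology
# -> restraints (auto-detected or user-imposed) -> restrained energy
# minimization -> refined structure, wrapped in a classed result object.

as_structure <- function(input, params) {
  if (inherits(input, "rna_structure")) input else read_pdb(input)
}

make_system <- function(topology, restraints, params, config, x0) {
  # memoize the last evaluation: the minimizer asks for f, gradient and
  # the per-term breakdown at the same point in close succession
  last_x <- NULL
  last_eb <- NULL
  eval_at <- function(x) {
    if (is.null(last_x) || !identical(x, last_x)) {
      last_eb <<- total_energy(topology, matrix(x, ncol = 3), restraints,
                               params, config)
      last_x <<- x
    }
    last_eb
  }
  f <- function(x) unclass(eval_at(x))[["total"]]
  g <- function(x) as.numeric(attr(eval_at(x), "gradient"))
  breakdown <- function(x) {
    v <- unclass(eval_at(x))
    attr(v, "gradient") <- NULL
    v
  }
  list(f = f, g = g, breakdown = breakdown, x0 = as.numeric(x0))
}

#' Refine a nucleic acid structure by restrained energy minimization
#'
#' The full pipeline: read the model (PDB path, text or
#' \code{rna_structure}), normalize atom names, complete hydrogens, build
#' the topology, assemble the restraint set (Watson-Crick pairs detected
#' geometrically, or imposed verbatim from a Vienna string / contact
#' list; explicit hydrogen bonds; base-pair co-planarity; backbone
#' regularization against the conformer library; optional custom
#' springs), then minimize the total energy with the configured
#' algorithm.
#'
#' @param input PDB file path, PDB text, or an \code{rna_structure}.
#' @param params Parameter set (default: packaged).
#' @param config Named list (or parsed config) overriding
#'   \code{\link{default_config}} entries.
#' @param ss Optional Vienna dot-bracket string; disables automatic
#'   base-pair detection.
#' @param contacts Optional contact-list text; disables automatic
#'   detection.
#' @param restraints Optional custom-restraint text
#'   (see \code{\link{parse_restraint_file}}).
#' @param library Optional \code{conformer_library}.
#' @return An object of class \code{rna_refit} with the refined
#'   structure, per-iteration energy trace, initial/final breakdowns,
#'   termination status and the frozen restraint set. Methods:
#'   \code{print}, \code{summary}, \code{plot}.
#' @examples
#' \donttest{
#' dx <- generate_aform_duplex("GGCGCC")
#' fit <- refine(dx, config = list(max_steps = 25, solvent = "vacuum"))
#' summary(fit)
#' }
#' @export
refine <- function(input, params = load_default_params(), config = list(),
                   ss = NULL, contacts = NULL, restraints = NULL,
                   library = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L)
    parse_config(config) else merge_config(config)
  s <- as_structure(input, params)
  s <- add_hydrogens(s, params)
  topo <- build_topology(s, params)
  rset <- build_restraints(s, params, cfg, ss = ss, contacts = contacts,
                           restraint_text = restraints, library = library)
  sys <- make_system(topo, rset, params, cfg, get_coords(s))
  minimizer <- if (identical(cfg$algorithm, "sd")) minimize_sd
               else minimize_prcg
  t0 <- Sys.time()
  mr <- minimizer(sys, cfg)
  out <- list(structure = set_coords(s, matrix(mr$x, ncol = 3)),
              initial = sys$breakdown(sys$x0),
              final = sys$breakdown(mr$x),
              trace = mr$trace, termination = mr$termination,
              iterations = mr$iterations, grad_norm = mr$grad_norm,
              restraints = rset, config = cfg,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              call = match.call())
  class(out) <- "rna_refit"
  out
}

#' Single-point energy score of a structure
#'
#' The scoring mode of the pipeline: identical setup to
#' \code{\link{refine}} (including startup restraint detection) but no
#' minimization - one energy evaluation with the per-term breakdown.
#'
#' @inheritParams refine
#' @param topology Optional reused \code{rna_topology} (must match the
#'   structure's atoms).
#' @return An \code{energy_breakdown}.
#' @export
score_structure <- function(input, params = load_default_params(),
                            config = list(), ss = NULL, contacts = NULL,
                            restraints = NULL, library = NULL,
                            topology = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L)
    parse_config(config) else merge_config(config)
  s <- as_structure(input, params)
  if (is.null(topology)) {
    s <- add_hydrogens(s, params)
    topology <- build_topology(s, params)
  } else if (topology$n != nrow(s$atoms))
    stop("supplied topology does not match the structure", call. = FALSE)
  rset <- build_restraints(s, params, cfg, ss = ss, contacts = contacts,
                           restraint_text = restraints, library = library)
  total_energy(topology, get_coords(s), rset, params, cfg)
}

#' @export
print.rna_refit <- function(x, ...) {
  cat("Refined nucleic acid structure (", x$termination, " after ",
      x$iterations, " iterations)\n", sep = "")
  cat(sprintf("  energy: %.3f -> %.3f kcal/mol\n",
              x$initial[["total"]], x$final[["total"]]))
  cat(sprintf("  RMS gradient: %.4f kcal/mol/A\n", x$grad_norm))
  cat("  restraints: ", NROW(x$restraints$pairs), " base pairs, ",
      NROW(x$restraints$hbonds), " H-bonds, ",
      length(x$restraints$backbone), " backbone targets\n", sep = "")
  invisible(x)
}

#' @export
summary.rna_refit <- function(object, ...) {
  cat("Restrained energy refinement\n")
  cat("  termination: ", object$termination, " (",
      object$iterations, " iterations, ",
      sprintf("%.1f", object$elapsed), " s)\n", sep = "")
  m <- rbind(initial = object$initial, final = object$final)
  print(round(m, 3))
  invisible(object)
}

#' Plot the per-term energy trace of a refinement
#'
#' @param x An \code{rna_refit}.
#' @param terms Which trace columns to draw (default: total).
#' @param ... Passed to \code{matplot}.
#' @export
plot.rna_refit <- function(x, terms = "total", ...) {
  tr <- x$trace[, terms, drop = FALSE]
  graphics::matplot(seq_len(nrow(tr)) - 1L, tr, type = "l", lty = 1,
                    xlab = "iteration", ylab = "energy (kcal/mol)", ...)
  if (ncol(tr) > 1L)
    graphics::legend("topright", legend = colnames(tr), lty = 1,
                     col = seq_len(ncol(tr)))
  invisible(x)
}
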