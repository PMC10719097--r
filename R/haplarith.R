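# The model front end: haplarith() fits the trio-seeded haplarithm model of
# a quartet and returns a classed object with the usual accessor methods.

#' Fit trio-based haplarithms and call aberrations
#'
#' The central fitting function: phases the parents with the CV seed,
#' screens both tissues for maternal contamination, builds the segmented
#' P1/P2/M1/M2 haplarithms at the given PCF penalty and calls chromosomal
#' aberrations with parental origin, segregational origin and mosaic
#' fraction.
#'
#' @param quartet a `"trio_quartet"` (from [simulate_quartet()] or
#'   [read_final_report()]).
#' @param gamma PCF breakpoint penalty on variance-standardized residuals
#'   (default 14).
#' @param min_snps minimal informative SNPs per series per chromosome.
#' @param f_min mosaic-fraction floor below which calls are suppressed.
#' @param tissues tissues to analyze; defaults to CV and, when present, EM.
#' @param monosomy_origin monosomy labelling convention, `"lost"` or
#'   `"retained"` (see [call_aberrations()]).
#' @param centromeres optional centromere table
#'   (default [centromere_positions()]).
#' @param ... further arguments passed to [call_aberrations()].
#' @return an object of class `"haplarith"` with components `haplarithms`
#'   (per tissue), `calls`, `contamination`, `phase` and `params`.
#' @examples
#' qt <- simulate_quartet(
#'   aberration_spec("trisomy", chromosome = "16", parent = "maternal",
#'                   seg_origin = "MI"),
#'   probe_map = default_probe_map(400, chromosomes = c("14", "15", "16")),
#'   noise = noise_model(baf_sd = 0.01), seed = 7)
#' fit <- haplarith(qt)
#' fit$calls
#' @export
haplarith <- function(quartet, gamma = 14, min_snps = 20, f_min = 0.10,
                      tissues = NULL, monosomy_origin = "lost",
                      centromeres = NULL, ...) {
  stopifnot(inherits(quartet, "trio_quartet"))
  if (is.null(tissues))
    tissues <- if (is.null(quartet$em)) "CV" else c("CV", "EM")
  phase <- phase_with_seed(quartet)
  contamination <- lapply(stats::setNames(tissues, tissues), function(t)
    estimate_maternal_contamination(quartet, t, phase = phase))
  haplarithms <- lapply(stats::setNames(tissues, tissues), function(t)
    build_haplarithm(quartet, t, gamma = gamma, min_snps = min_snps,
                     phase = phase))
  calls <- call_aberrations(quartet, tissues = tissues, gamma = gamma,
                            min_snps = min_snps, f_min = f_min,
                            monosomy_origin = monosomy_origin,
                            centromeres = centromeres, phase = phase,
                            haplarithms = haplarithms, ...)
  structure(list(quartet = quartet, phase = phase,
                 contamination = contamination,
                 haplarithms = haplarithms, calls = calls,
                 params = list(gamma = gamma, min_snps = min_snps,
                               f_min = f_min,
                               monosomy_origin = monosomy_origin)),
            class = "haplarith")
}

#' @export
print.haplarith <- function(x, ...) {
  pm <- x$quartet$probe_map
  cat("Trio-seeded haplarithm fit\n")
  cat(sprintf("  %d probes on %d chromosome(s); gamma = %g\n",
              nrow(pm), length(unique(pm$chromosome)), x$params$gamma))
  cat(sprintf("  Mendelian inconsistency rate: %.2f%%\n",
              100 * x$phase$inconsistency_rate))
  for (t in names(x$contamination)) {
    co <- x$contamination[[t]]
    cat(sprintf("  %s maternal contamination: %.2f%s\n", t, co$c_hat,
                if (co$complete_flag) "  [COMPLETE - excluded]" else ""))
  }
  ex <- attr(x$calls, "excluded")
  if (length(ex) > 0) cat("  excluded tissue(s):", paste(ex, collapse = ", "), "\n")
  if (nrow(x$calls) == 0) cat("  No aberration calls\n")
  else {
    cat(sprintf("  %d aberration call(s):\n", nrow(x$calls)))
    for (i in seq_len(nrow(x$calls))) {
      cl <- x$calls[i, ]
      cat(sprintf("    %s chr%s %s %s (%s, %s), f = %.2f\n",
                  cl$tissue, cl$chromosome, cl$size_class, cl$copy_state,
                  cl$parental_origin, cl$segregational_origin,
                  cl$mosaic_fraction))
    }
  }
  invisible(x)
}

#' @export
summary.haplarith <- function(object, ...) {
  pm <- object$quartet$probe_map
  chroms <- intersect(.CHROMS, unique(pm$chromosome))
  rows <- list()
  for (t in names(object$haplarithms)) {
    h <- object$haplarithms[[t]]
    for (ch in chroms) {
      dv <- compute_d_values(h, ch)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = t, chromosome = ch, d_pat = dv$d_pat, d_mat = dv$d_mat,
        mean_logr = dv$mean_logr, stringsAsFactors = FALSE)
    }
  }
  out <- list(d_values = do.call(rbind, rows), calls = object$calls,
              contamination = object$contamination,
              inconsistency_rate = object$phase$inconsistency_rate)
  class(out) <- "summary.haplarith"
  out
}

#' @export
print.summary.haplarith <- function(x, ...) {
  cat("Per-chromosome haplarithm band separations:\n")
  print(format(x$d_values, digits = 3), row.names = FALSE)
  cat(sprintf("\nMendelian inconsistency rate: %.2f%%\n",
              100 * x$inconsistency_rate))
  cat(sprintf("\n%d aberration call(s)\n", nrow(x$calls)))
  if (nrow(x$calls) > 0) print(format(x$calls, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.haplarith <- function(object, ...) {
  summary(object)$d_values
}

#' Residuals of the haplarithm fit
#'
#' Mirrored BAF values minus their fitted segment means, per tissue and
#' series.
#'
#' @param object a `"haplarith"` fit.
#' @param tissue tissue to extract (default first fitted).
#' @param ... unused.
#' @return data frame: `chromosome`, `position`, `series`, `residual`.
#' @export
residuals.haplarith <- function(object, tissue = NULL, ...) {
  if (is.null(tissue)) tissue <- names(object$haplarithms)[1]
  tab <- export_haplarithm(object$haplarithms[[tissue]])
  data.frame(chromosome = tab$chromosome, position = tab$position,
             series = tab$series, residual = tab$baf - tab$segment_mean,
             stringsAsFactors = FALSE)
}

#' Plot a haplarithm
#'
#' Three stacked base-graphics panels for one chromosome of one tissue: the
#' paternal series (P1 blue, P2 red), the maternal series (M1 blue, M2
#' red), each with fitted segment means, and the logR track.
#'
#' @param x a `"haplarith"` fit.
#' @param chromosome chromosome to plot.
#' @param tissue tissue (default first fitted).
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.haplarith <- function(x, chromosome = NULL, tissue = NULL, ...) {
  if (is.null(tissue)) tissue <- names(x$haplarithms)[1]
  h <- x$haplarithms[[tissue]]
  if (is.null(chromosome)) chromosome <- names(h$chromosomes)[1]
  chromosome <- normalize_chrom(chromosome)
  hc <- h$chromosomes[[chromosome]]
  if (is.null(hc)) stop("chromosome not in fit")
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  panel <- function(s1, s2, lab) {
    xlim <- range(c(s1$position, s2$position, 0)) / 1e6
    graphics::plot(NA, xlim = xlim, ylim = c(0, 1), xlab = "",
                   ylab = "mirrored BAF", main = lab)
    draw <- function(s, col) {
      graphics::points(s$position / 1e6, s$baf, col = col, pch = 16,
                       cex = 0.3)
      if (!is.null(s$segments))
        graphics::segments(s$segments$start_bp / 1e6, s$segments$mean,
                           s$segments$end_bp / 1e6, s$segments$mean,
                           col = col, lwd = 3)
    }
    draw(s1, "blue"); draw(s2, "red")
  }
  panel(hc$series$P1, hc$series$P2,
        sprintf("%s chr%s paternal haplarithm (P1/P2)", tissue, chromosome))
  panel(hc$series$M1, hc$series$M2,
        sprintf("%s chr%s maternal haplarithm (M1/M2)", tissue, chromosome))
  graphics::plot(hc$logr_position / 1e6, hc$logr, pch = 16, cex = 0.3,
                 col = "grey40", xlab = "position (Mb)", ylab = "logR",
                 main = "logR", ylim = c(-1.5, 1.5))
  if (!is.null(hc$logr_segments))
    graphics::segments(hc$logr_segments$start_bp / 1e6,
                       hc$logr_segments$mean,
                       hc$logr_segments$end_bp / 1e6,
                       hc$logr_segments$mean, col = "black", lwd = 3)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
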