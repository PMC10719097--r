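# Core haplarithmisis transforms: informative-SNP categorization, CV-seeded
# Mendelian phasing, BAF mirroring and exact piecewise-constant-fitting
# segmentation of the four phased BAF series (P1, P2, M1, M2).

.gt_dose <- function(gt) {
  d <- rep(NA_integer_, length(gt))
  d[gt == "AA"] <- 0L; d[gt == "AB"] <- 1L; d[gt == "BB"] <- 2L
  d
}

#' Categorize SNPs by parental informativeness
#'
#' An informative SNP has one heterozygous and one homozygous parent:
#' `paternal_informative` when the father is AB and the mother homozygous,
#' `maternal_informative` symmetrically.  Double heterozygous SNPs
#' (`both_het`) carry no parent-of-origin information and are excluded from
#' the haplarithms; any no-call makes the SNP `missing`.
#'
#' @param mother_gt,father_gt character vectors of `AA`/`AB`/`BB`/`NC` calls.
#' @return character vector with levels `paternal_informative`,
#'   `maternal_informative`, `both_het`, `uninformative`, `missing`.
#' @export
classify_informative_snps <- function(mother_gt, father_gt) {
  if (length(mother_gt) != length(father_gt))
    stop("genotype tracks must be aligned")
  m <- .gt_dose(mother_gt); f <- .gt_dose(father_gt)
  out <- rep("uninformative", length(m))
  out[is.na(m) | is.na(f)] <- "missing"
  out[!is.na(m) & !is.na(f) & m == 1L & f == 1L] <- "both_het"
  out[!is.na(m) & !is.na(f) & f == 1L & m != 1L] <- "paternal_informative"
  out[!is.na(m) & !is.na(f) & m == 1L & f != 1L] <- "maternal_informative"
  out
}

#' Phase the parental genotypes with the CV genotype as seed
#'
#' At every informative SNP the transmitted allele of the heterozygous
#' parent is deduced Mendelianly from the CV genotype and the homozygous
#' parent's genotype.  The deduced transmitted allele defines homolog H1 of
#' the heterozygous parent, which fixes the subcategory of the SNP --
#' P1/M1 when the transmitted allele equals the homozygous parent's allele
#' (the seed child is then homozygous there), P2/M2 otherwise -- and the
#' mirror flag (set when the phased parental genotype reads BA, i.e. the
#' transmitted allele is B).
#'
#' SNPs whose CV call is Mendelian-inconsistent with the parents (the child
#' is homozygous for an allele the homozygous parent does not carry) are
#' flagged and excluded; their per-chromosome counts are kept as
#' diagnostics, since their distribution over the paternal/maternal
#' categories is informative about full monosomies and uniparental
#' disomies.  A genome-wide inconsistency rate above `max_inconsistency`
#' aborts with a non-paternity/contamination error.
#'
#' @param quartet a `"trio_quartet"`.
#' @param max_inconsistency maximal tolerated genome-wide Mendelian
#'   inconsistency rate (default 0.05).
#' @return a list of class `"seed_phase"` with elements `snps` (data frame:
#'   `idx`, `chromosome`, `position`, `category`, `series`, `mirror`,
#'   `transmitted`) and `diagnostics` (per-chromosome informative and
#'   inconsistent counts per category).
#' @export
phase_with_seed <- function(quartet, max_inconsistency = 0.05) {
  pm <- quartet$probe_map
  mo <- .gt_dose(quartet$mother$gtype)
  fa <- .gt_dose(quartet$father$gtype)
  cv <- .gt_dose(quartet$cv$gtype)
  cat <- classify_informative_snps(quartet$mother$gtype,
                                   quartet$father$gtype)
  phase_one <- function(which_cat, het, hom) {
    i <- which(cat == which_cat)
    hom_allele <- hom[i] %/% 2L                     # 0 or 1
    cvd <- cv[i]
    transmitted <- rep(NA_integer_, length(i))
    fail <- rep(FALSE, length(i))
    is_het <- !is.na(cvd) & cvd == 1L
    is_hom <- !is.na(cvd) & cvd != 1L
    transmitted[is_het] <- 1L - hom_allele[is_het]
    transmitted[is_hom] <- cvd[is_hom] %/% 2L
    fail[is_hom] <- (cvd[is_hom] %/% 2L) != hom_allele[is_hom]
    transmitted[fail] <- NA_integer_
    list(idx = i, transmitted = transmitted, fail = fail,
         hom_allele = hom_allele)
  }
  pat <- phase_one("paternal_informative", fa, mo)
  mat <- phase_one("maternal_informative", mo, fa)

  build <- function(ph, cat_lab, s1, s2) {
    ok <- !is.na(ph$transmitted)
    if (!any(ok))
      return(data.frame(idx = integer(), chromosome = character(),
                        position = numeric(), category = character(),
                        series = character(), mirror = logical(),
                        transmitted = integer(), stringsAsFactors = FALSE))
    data.frame(
      idx = ph$idx[ok],
      chromosome = pm$chromosome[ph$idx[ok]],
      position = pm$position[ph$idx[ok]],
      category = cat_lab,
      series = ifelse(ph$transmitted[ok] == ph$hom_allele[ok], s1, s2),
      mirror = ph$transmitted[ok] == 1L,
      transmitted = ph$transmitted[ok],
      stringsAsFactors = FALSE)
  }
  snps <- rbind(build(pat, "pat", "P1", "P2"),
                build(mat, "mat", "M1", "M2"))
  snps <- snps[order(snps$idx), , drop = FALSE]
  rownames(snps) <- NULL

  tally <- function(ph) {
    ch <- pm$chromosome[ph$idx]
    data.frame(
      chromosome = intersect(.CHROMS, unique(pm$chromosome)),
      n = as.integer(table(factor(ch, intersect(.CHROMS, unique(pm$chromosome))))),
      n_fail = as.integer(table(factor(ch[ph$fail],
                                       intersect(.CHROMS, unique(pm$chromosome))))),
      stringsAsFactors = FALSE)
  }
  diag <- list(pat = tally(pat), mat = tally(mat))
  n_inf <- sum(diag$pat$n) + sum(diag$mat$n)
  n_fail <- sum(diag$pat$n_fail) + sum(diag$mat$n_fail)
  rate <- if (n_inf > 0) n_fail / n_inf else 0
  if (rate > max_inconsistency)
    stop(sprintf(
      "Mendelian inconsistency rate %.1f%% exceeds %.1f%%: non-paternity or sample contamination suspected",
      100 * rate, 100 * max_inconsistency))
  structure(list(snps = snps, diagnostics = diag,
                 inconsistency_rate = rate,
                 informative_idx = list(pat = pat$idx, mat = mat$idx),
                 fail_idx = list(pat = pat$idx[pat$fail],
                                 mat = mat$idx[mat$fail])),
            class = "seed_phase")
}

#' Mirror a BAF value around the 0.5 axis
#'
#' @param baf BAF value(s) in `[0, 1]`.
#' @param mirror_flag logical; where `TRUE` the value is reflected
#'   (`1 - baf`), elsewhere returned unchanged.
#' @return oriented BAF value(s).
#' @export
mirror_baf <- function(baf, mirror_flag) {
  flag <- rep_len(as.logical(mirror_flag), length(baf))
  out <- baf
  out[flag] <- 1 - baf[flag]
  out
}

#' Exact piecewise-constant-fitting (PCF) segmentation
#'
#' Finds the segmentation minimizing the penalized least-squares cost
#' \deqn{\sum_{segments} \sum_i (y_i - \bar y_{seg})^2 / s^2 + \gamma K}
#' where `K` is the number of breakpoints, solved exactly by dynamic
#' programming in O(n^2).  By default the residuals are standardized by a
#' robust noise estimate `s` (the median absolute deviation of first
#' differences divided by sqrt(2)), so that `gamma` is comparable across
#' noise levels; pass `standardize = FALSE` to apply `gamma` to raw squared
#' residuals.  Ties are broken toward fewer segments.
#'
#' @param y numeric series (ordered along the chromosome).
#' @param gamma breakpoint penalty, `>= 0`.
#' @param standardize standardize residuals by the robust noise estimate.
#' @param min_sd lower floor for the noise estimate (guards noise-free
#'   series).
#' @param positions optional base-pair positions, attached to the segments.
#' @return data frame of segments: `start_idx`, `end_idx` (1-based inclusive
#'   indices into `y`), `start_bp`, `end_bp` (when `positions` given), `n`,
#'   `mean`.
#' @export
pcf_segment <- function(y, gamma, standardize = TRUE, min_sd = 1e-4,
                        positions = NULL) {
  if (gamma < 0) stop("gamma must be >= 0")
  n <- length(y)
  if (n == 0 || any(!is.finite(y))) stop("series must be non-empty and finite")
  s <- 1
  if (standardize && n >= 3) {
    s <- stats::mad(diff(y)) / sqrt(2)
    s <- max(s, min_sd)
  }
  z <- y / s
  cs <- c(0, cumsum(z)); css <- c(0, cumsum(z^2))
  # best[j]: optimal cost of z[1..j]; keep segment count for tie-breaking
  best <- numeric(n + 1); cnt <- integer(n + 1); prev <- integer(n + 1)
  best[1] <- 0; cnt[1] <- 0
  for (j in seq_len(n)) {
    i <- seq_len(j)                      # candidate segment starts
    len <- j - i + 1
    sse <- (css[j + 1] - css[i]) - (cs[j + 1] - cs[i])^2 / len
    cost <- best[i] + sse + gamma * (i > 1)
    k <- cnt[i] + 1L
    # minimal cost; ties (within numerical tolerance) -> fewest segments,
    # then the longest last segment (smallest i)
    b <- which.min(cost)
    tie <- which(cost <= cost[b] + 1e-9)
    if (length(tie) > 1) b <- tie[order(k[tie], i[tie])][1]
    best[j + 1] <- cost[b]; cnt[j + 1] <- k[b]; prev[j + 1] <- b
  }
  ends <- integer(0); j <- n
  while (j > 0) { ends <- c(j, ends); j <- prev[j + 1] - 1 }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg <- data.frame(start_idx = as.integer(starts),
                    end_idx = as.integer(ends))
  seg$n <- seg$end_idx - seg$start_idx + 1
  seg$mean <- vapply(seq_len(nrow(seg)), function(r)
    mean(y[seg$start_idx[r]:seg$end_idx[r]]), numeric(1))
  if (!is.null(positions)) {
    seg$start_bp <- positions[seg$start_idx]
    seg$end_bp <- positions[seg$end_idx]
  }
  seg
}

SERIES_NAMES <- c("P1", "P2", "M1", "M2")

#' Build the parental haplarithms of a target tissue
#'
#' Routes the target sample's BAF values into the four phased subcategory
#' series (P1, P2, M1, M2), mirrors them, and segments each series (and the
#' target logR track) by exact PCF at the given `gamma`.  The EM sample is
#' interpreted against the CV-seeded phase.  A series with fewer than
#' `min_snps` informative SNPs on a chromosome is marked uninformative and
#' carries no segments.
#'
#' @param quartet a `"trio_quartet"`.
#' @param target `"CV"` or `"EM"`.
#' @param gamma PCF breakpoint penalty (default 14, applied to
#'   variance-standardized residuals).
#' @param min_snps minimal informative SNPs per series per chromosome.
#' @param phase optional precomputed [phase_with_seed()] result.
#' @return an object of class `"haplarithm"`: per-chromosome list of series
#'   (`idx`, `position`, `baf` mirrored, `segments`), logR segments, target
#'   label and the phase diagnostics.
#' @export
build_haplarithm <- function(quartet, target = c("CV", "EM"), gamma = 14,
                             min_snps = 20, phase = NULL) {
  target <- match.arg(target)
  if (target == "EM" && is.null(quartet$em)) stop("quartet has no EM sample")
  if (is.null(phase)) phase <- phase_with_seed(quartet)
  sample <- if (target == "CV") quartet$cv else quartet$em
  pm <- quartet$probe_map
  chroms <- intersect(.CHROMS, unique(pm$chromosome))
  snps <- phase$snps
  out <- vector("list", length(chroms)); names(out) <- chroms
  cidx <- chrom_index(pm)
  for (ch in chroms) {
    sl <- vector("list", length(SERIES_NAMES)); names(sl) <- SERIES_NAMES
    for (sn in SERIES_NAMES) {
      rows <- snps[snps$chromosome == ch & snps$series == sn, , drop = FALSE]
      baf <- mirror_baf(sample$baf[rows$idx], rows$mirror)
      keep <- !is.na(baf)
      rows <- rows[keep, , drop = FALSE]; baf <- baf[keep]
      if (nrow(rows) < min_snps) {
        sl[[sn]] <- list(idx = rows$idx, position = rows$position, baf = baf,
                         segments = NULL, informative = FALSE)
      } else {
        seg <- pcf_segment(baf, gamma, positions = rows$position)
        sl[[sn]] <- list(idx = rows$idx, position = rows$position, baf = baf,
                         segments = seg, informative = TRUE)
      }
    }
    li <- cidx[[ch]]
    lr <- sample$logr[li]
    lseg <- if (sum(is.finite(lr)) >= min_snps)
      pcf_segment(lr[is.finite(lr)], gamma,
                  positions = pm$position[li][is.finite(lr)]) else NULL
    out[[ch]] <- list(series = sl, logr_segments = lseg,
                      logr = lr, logr_position = pm$position[li])
  }
  structure(list(chromosomes = out, target = target, gamma = gamma,
                 min_snps = min_snps, phase = phase),
            class = "haplarithm")
}

#' Export a haplarithm as a tidy table
#'
#' One row per informative SNP: chromosome, position, series, mirrored BAF
#' and the fitted segment mean, suitable for plotting.
#'
#' @param h a `"haplarithm"`.
#' @param path optional path to write a TSV; when `NULL` the data frame is
#'   returned invisibly only.
#' @return the tidy data frame, invisibly.
#' @export
export_haplarithm <- function(h, path = NULL) {
  rows <- list()
  for (ch in names(h$chromosomes)) {
    for (sn in SERIES_NAMES) {
      s <- h$chromosomes[[ch]]$series[[sn]]
      if (length(s$idx) == 0) next
      fit <- rep(NA_real_, length(s$idx))
      if (!is.null(s$segments)) {
        for (r in seq_len(nrow(s$segments)))
          fit[s$segments$start_idx[r]:s$segments$end_idx[r]] <-
            s$segments$mean[r]
      }
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = ch, position = s$position, series = sn,
        baf = s$baf, segment_mean = fit, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
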