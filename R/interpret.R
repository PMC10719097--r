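# Interpretation of haplarithms: d-value measurement, copy-state and
# parental-origin classification against allele-count templates,
# MI/MII/mitotic discrimination from the homolog composition around the
# centromere, mosaic-fraction estimation and maternal-contamination
# detection.

weighted_median <- function(x, w) {
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0) return(NA_real_)
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# fitted segment mean per SNP of one series (NA when unsegmented)
.series_fit <- function(s) {
  fit <- rep(NA_real_, length(s$idx))
  if (!is.null(s$segments)) {
    for (r in seq_len(nrow(s$segments)))
      fit[s$segments$start_idx[r]:s$segments$end_idx[r]] <- s$segments$mean[r]
  }
  fit
}

# bp boundaries separating consecutive segments of one series
.series_breaks <- function(s) {
  if (is.null(s$segments) || nrow(s$segments) < 2) return(numeric(0))
  (s$segments$end_bp[-nrow(s$segments)] + s$segments$start_bp[-1]) / 2
}

#' Measure the haplarithm band separations over an interval
#'
#' `d_pat` is the separation between the fitted band levels of the two
#' paternal series (P1 vs P2), `d_mat` the maternal analogue; both are
#' evaluated as base-pair-weighted medians of the per-region level
#' differences, over the regions (delimited by the union of the two series'
#' PCF breakpoints) where *both* series carry SNPs.  When only one series
#' of a pair carries a fitted band in the interval, a single band exists and
#' the separation is 0; when neither does, the value is `NA` (not
#' determined).  `mean_logr` is the mean target logR over the interval.
#'
#' @param h a `"haplarithm"`.
#' @param chromosome chromosome label.
#' @param start,end 1-based inclusive interval; defaults to the whole
#'   chromosome.
#' @return list of class `"d_values"`: `d_pat`, `d_mat`, `mean_logr` and
#'   `bands` (per parent: band levels `l1`, `l2` and SNP counts).
#' @export
compute_d_values <- function(h, chromosome, start = NULL, end = NULL) {
  chromosome <- normalize_chrom(chromosome)
  ch <- h$chromosomes[[chromosome]]
  if (is.null(ch)) stop("chromosome ", chromosome, " not in haplarithm")
  if (is.null(start)) start <- -Inf
  if (is.null(end)) end <- Inf

  pair_d <- function(s1, s2) {
    in1 <- s1$position >= start & s1$position <= end
    in2 <- s2$position >= start & s2$position <= end
    f1 <- .series_fit(s1)[in1]; p1 <- s1$position[in1]
    f2 <- .series_fit(s2)[in2]; p2 <- s2$position[in2]
    ok1 <- is.finite(f1); ok2 <- is.finite(f2)
    n1 <- sum(ok1); n2 <- sum(ok2)
    l1 <- weighted_median(f1[ok1], rep(1, n1))
    l2 <- weighted_median(f2[ok2], rep(1, n2))
    if (n1 < 5 && n2 < 5)
      return(list(d = NA_real_, l1 = l1, l2 = l2, n1 = n1, n2 = n2))
    if (n1 < 5 || n2 < 5) {
      # a single fitted band: separation 0 -- but only when the minority
      # series is genuinely depleted of SNPs (full aberrations route or
      # exclude entire subcategories).  Depletion is judged on PRESENT
      # SNPs: a series that holds SNPs but fell below the segmentation
      # minimum is undetermined, not collapsed.
      m1 <- length(p1); m2 <- length(p2)
      m_min <- min(m1, m2); m_max <- max(m1, m2)
      d0 <- if (m_max >= 10 && m_min <= max(2, 0.1 * m_max)) 0 else NA_real_
      return(list(d = d0, l1 = l1, l2 = l2, n1 = n1, n2 = n2))
    }
    # regions bounded by the union of both series' breakpoints
    brk <- sort(unique(c(.series_breaks(s1), .series_breaks(s2))))
    brk <- brk[brk > start & brk < end]
    bounds <- c(max(start, min(c(p1, p2)) - 1), brk, min(end, max(c(p1, p2))))
    dr <- wr <- numeric(0)
    for (r in seq_len(length(bounds) - 1)) {
      a <- bounds[r]; b <- bounds[r + 1]
      c1 <- ok1 & p1 > a & p1 <= b
      c2 <- ok2 & p2 > a & p2 <= b
      if (sum(c1) >= 3 && sum(c2) >= 3) {
        dr <- c(dr, abs(mean(f1[c1]) - mean(f2[c2])))
        wr <- c(wr, b - a)
      }
    }
    d <- if (length(dr) > 0) weighted_median(dr, wr) else abs(l1 - l2)
    list(d = d, l1 = l1, l2 = l2, n1 = n1, n2 = n2)
  }
  P <- pair_d(ch$series$P1, ch$series$P2)
  M <- pair_d(ch$series$M1, ch$series$M2)
  inl <- ch$logr_position >= start & ch$logr_position <= end &
    is.finite(ch$logr)
  structure(list(d_pat = P$d, d_mat = M$d,
                 mean_logr = if (any(inl)) mean(ch$logr[inl]) else NA_real_,
                 bands = list(P = P, M = M)),
            class = "d_values")
}

# Expected (d_pat, d_mat, logR) triples per copy state, parental origin and
# mosaic fraction, from allele-count enumeration of the mixture bands.  The
# "own0" variants carry d = 0 for the origin parent's own series: on a
# chromosome whose origin-parent composition is both-homolog (BPH)
# throughout, CV-self-seeded phasing routes every informative SNP into the
# heterozygous-looking series and the own-series separation collapses.
.template_cache <- new.env(parent = emptyenv())

copy_state_templates <- function(f_grid = seq(0.02, 1, 0.02)) {
  key <- paste(range(f_grid), length(f_grid), collapse = "_")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  f <- f_grid
  d_hi3 <- (1 + f) / (2 + f); d_lo3 <- 1 / (2 + f); lr3 <- log2(1 + f / 2)
  d_hi4 <- (1 + 2 * f) / (2 + 2 * f); d_lo4 <- 1 / (2 + 2 * f)
  lr4 <- log2(1 + f)
  d_hiL <- 1 / (2 - f); d_loL <- (1 - f) / (2 - f); lrL <- log2(1 - f / 2)
  one <- function(state, origin, cn, dp, dm, lr, variant = "std")
    data.frame(state = state, origin = origin, f = f, cn = cn,
               d_pat = dp, d_mat = dm, logr = lr, variant = variant,
               stringsAsFactors = FALSE)
  tmpl <- rbind(
    data.frame(state = "disomy", origin = "ND", f = 0, cn = 2,
               d_pat = 0.5, d_mat = 0.5, logr = 0, variant = "std",
               stringsAsFactors = FALSE),
    one("gain", "maternal", 3, d_hi3, d_lo3, lr3),
    one("gain", "paternal", 3, d_lo3, d_hi3, lr3),
    one("gain", "maternal", 3, d_hi3, 0, lr3, "own0"),
    one("gain", "paternal", 3, 0, d_hi3, lr3, "own0"),
    one("gain", "maternal", 4, d_hi4, d_lo4, lr4),
    one("gain", "paternal", 4, d_lo4, d_hi4, lr4),
    one("loss", "maternal", 1, d_loL, d_hiL, lrL),
    one("loss", "paternal", 1, d_hiL, d_loL, lrL),
    one("neutral_UPD", "maternal", 2, (1 + f) / 2, (1 - f) / 2, 0),
    one("neutral_UPD", "paternal", 2, (1 - f) / 2, (1 + f) / 2, 0),
    # degenerate full-aberration presentations under CV-self-seeded
    # phasing: the failing/absent series collapse and d reads (0, 0);
    # origin is then resolved from the Mendelian-inconsistency side
    data.frame(state = c("loss", "neutral_UPD"), origin = "ND", f = 1,
               cn = c(1, 2), d_pat = 0, d_mat = 0, logr = c(-1, 0),
               variant = "full", stringsAsFactors = FALSE))
  .template_cache[[key]] <- tmpl
  tmpl
}

#' Classify the copy state and parental origin of an interval
#'
#' Nearest-template classification of the measured `(d_pat, d_mat, logR)`
#' triple over the expected triples for disomy, maternal/paternal gains
#' (copy number 3 and 4), monosomies and isodisomic UPD across the mosaic
#' fraction grid.  Templates are generated by allele-count enumeration of
#' the mixture bands.  A template matches only when every comparable
#' component deviates by at most `tol_d` (d space) and `tol_logr` (logR);
#' otherwise the result is `ND`.  `NA` components (uninformative series,
#' e.g. the paternal series on chromosome X) are skipped.
#'
#' @param dvals a `"d_values"` object (or list with `d_pat`, `d_mat`,
#'   `mean_logr`).
#' @param tol_d tolerance in d space (default 0.08).
#' @param tol_logr tolerance in logR (default 0.15).
#' @return list: `copy_state` (`gain`, `loss`, `neutral_UPD`, `disomy` or
#'   `ND`), `parental_origin` (`maternal`, `paternal`, `ND`), `f` (template
#'   mosaic fraction), `copy_number`, `variant`, `score`.
#' @export
classify_copy_state <- function(dvals, tol_d = 0.08, tol_logr = 0.15) {
  tmpl <- copy_state_templates()
  obs <- c(dvals$d_pat, dvals$d_mat, dvals$mean_logr)
  tol <- c(tol_d, tol_d, tol_logr)
  exp_mat <- as.matrix(tmpl[, c("d_pat", "d_mat", "logr")])
  usable <- !is.na(obs)
  if (!any(usable[1:2]) || !usable[3])
    return(list(copy_state = "ND", parental_origin = "ND", f = NA_real_,
                copy_number = NA_integer_, variant = NA_character_,
                score = NA_real_))
  dev <- abs(sweep(exp_mat[, usable, drop = FALSE], 2, obs[usable]))
  within <- dev <= matrix(rep(tol[usable], each = nrow(dev)), nrow = nrow(dev))
  ok <- rowSums(within) == sum(usable)
  if (!any(ok))
    return(list(copy_state = "ND", parental_origin = "ND", f = NA_real_,
                copy_number = NA_integer_, variant = NA_character_,
                score = NA_real_))
  score <- sqrt(rowMeans(sweep(dev, 2, tol[usable], "/")^2))
  score[!ok] <- Inf
  # a double gain (CN 4) at fraction f/2 occupies the same band positions
  # as a single gain (CN 3) at f, so CN 4 is a strictly secondary
  # hypothesis: it is chosen only when no CN <= 3 template fits; ties
  # prefer the standard template variant
  b <- order(tmpl$cn == 4 & any(ok & tmpl$cn != 4), score,
             tmpl$variant != "std")[1]
  list(copy_state = tmpl$state[b], parental_origin = tmpl$origin[b],
       f = tmpl$f[b], copy_number = tmpl$cn[b], variant = tmpl$variant[b],
       score = score[b])
}

#' Mosaic fraction from the heterozygous-band shift
#'
#' Closed-form inversion of the allele-count mixture bands.  With a fraction
#' `f` of aberrant cells, the band of heterozygous-informative SNPs sits at
#' `(1+f)/(2+f)` for a trisomy, `(1-f)/(2-f)` for a monosomy and `(1+f)/2`
#' for an isodisomic UPD; given the measured shift `delta = |band - 0.5|`
#' this inverts to `f = 4d/(1-2d)`, `f = 4d/(1+2d)` and `f = 2d`
#' respectively (and `f = 2d/(1-2d)` for a double gain, copy number 4).
#' Results are clipped to `[0, 1]`.
#'
#' @param het_band_shift shift `delta` in `[0, 0.5]`.
#' @param copy_state `"gain"` (alias `"trisomy"`), `"loss"` (alias
#'   `"monosomy"`) or `"neutral_UPD"` (alias `"upd"`).
#' @param copy_number 3 (default) or 4 for gains.
#' @return estimated mosaic fraction in `[0, 1]`.
#' @export
estimate_mosaic_fraction <- function(het_band_shift, copy_state,
                                     copy_number = 3) {
  d <- het_band_shift
  if (is.na(d)) return(NA_real_)
  if (d < 0 || d > 0.5) stop("het band shift must lie in [0, 0.5]")
  st <- switch(copy_state,
               trisomy = "gain", gain = "gain",
               monosomy = "loss", loss = "loss",
               upd = "neutral_UPD", neutral_UPD = "neutral_UPD",
               stop("unknown copy state: ", copy_state))
  if (st == "gain" && d >= 0.5)
    stop("band shift ", d, " is impossible for state ", st)
  f <- switch(st,
    gain = if (copy_number == 4) 2 * d / (1 - 2 * d) else 4 * d / (1 - 2 * d),
    loss = 4 * d / (1 + 2 * d),
    neutral_UPD = 2 * d)
  min(1, max(0, f))
}

# region composition of the origin parent's series: single parental homolog
# (SPH) vs both parental homologs (BPH), given the mosaic fraction
.region_composition <- function(l1, l2, r1, f, cn = 3, tol = 0.08) {
  denom <- if (cn == 4) 2 + 2 * f else 2 + f
  fnum <- if (cn == 4) 2 * f else f
  sph <- c(0, 1 / denom)
  bph <- c(f / (2 + f), (1 + f) / (2 + f))
  if (is.na(r1)) return("ND")
  if (r1 < 0.2 || is.na(l1)) {
    # own-series depleted: self-seeded phasing routes all SNPs to the
    # het-looking series -- BPH presentation at high f
    if (!is.na(l2) && abs(l2 - (1 + f) / (2 + f)) <= tol) return("BPH")
    return("ND")
  }
  if (is.na(l1) || is.na(l2)) return("ND")
  d_sph <- max(abs(l1 - sph[1]), abs(l2 - sph[2]))
  d_bph <- max(abs(l1 - bph[1]), abs(l2 - bph[2]))
  if (min(d_sph, d_bph) > tol) return("ND")
  if (abs(d_sph - d_bph) < 0.02) return("ND")  # templates collide as f -> 0
  if (d_sph < d_bph) "SPH" else "BPH"
}

#' Infer the segregational origin of a gain
#'
#' Reconstructs which homologs of the contributing parent are present along
#' the chromosome from the band levels of that parent's own haplarithm
#' series.  Both parental homologs at the centromere (BPH) indicate a
#' meiosis I error; a single homolog (SPH) at the centromere with BPH in a
#' segment bounded by a crossover indicates meiosis II; SPH along the whole
#' chromosome indicates a mitotic error.  Copy-neutral UPD, monosomies and
#' segmental events carry a single homolog by construction and default to
#' mitotic unless BPH is detected.
#'
#' @param h a `"haplarithm"`.
#' @param call a one-row data frame (or list) with at least `chromosome`,
#'   `copy_state`, `parental_origin`, `mosaic_fraction`, `copy_number`,
#'   `start`, `end`.
#' @param centromeres named centromere coordinate vector
#'   (default [centromere_positions()]).
#' @param min_region_snps minimal SNPs per region to type its composition
#'   (default 4; a region must already have earned its own PCF segment).
#' @return `"MI"`, `"MII"`, `"mitotic"` or `"ND"`.
#' @export
infer_segregational_origin <- function(h, call, centromeres = NULL,
                                       min_region_snps = 4) {
  if (call$parental_origin == "ND") return("ND")
  if (call$copy_state %in% c("loss", "neutral_UPD")) return("mitotic")
  ch <- h$chromosomes[[normalize_chrom(call$chromosome)]]
  if (is.null(ch)) return("ND")
  if (is.null(centromeres)) centromeres <- centromere_positions()
  cen <- centromeres[[normalize_chrom(call$chromosome)]]
  own <- if (call$parental_origin == "maternal")
    list(ch$series$M1, ch$series$M2) else list(ch$series$P1, ch$series$P2)
  f <- call$mosaic_fraction
  if (is.na(f)) f <- 1
  cn <- if (!is.null(call$copy_number) && !is.na(call$copy_number))
    call$copy_number else 3
  s1 <- own[[1]]; s2 <- own[[2]]
  f1 <- .series_fit(s1); f2 <- .series_fit(s2)
  segmental <- !is.null(call$size_class) && !is.na(call$size_class) &&
    call$size_class == "segmental"
  if (segmental) {
    a <- call$start; b <- call$end
  } else {
    # homolog composition is a whole-chromosome property; do not let the
    # called interval (which may stop at an ineligible terminal region)
    # hide a distal both-homolog segment
    a <- min(c(s1$position, s2$position, call$start))
    b <- max(c(s1$position, s2$position, call$end))
  }
  brk <- sort(unique(c(.series_breaks(s1), .series_breaks(s2))))
  brk <- brk[brk > a & brk < b]
  bounds <- c(a - 1, brk, b)
  comp <- character(length(bounds) - 1)
  cen_dist <- rep(Inf, length(comp))
  for (r in seq_along(comp)) {
    lo <- bounds[r]; hi <- bounds[r + 1]
    c1 <- s1$position > lo & s1$position <= hi & is.finite(f1)
    c2 <- s2$position > lo & s2$position <= hi & is.finite(f2)
    n1 <- sum(c1); n2 <- sum(c2)
    if (n1 + n2 < min_region_snps) { comp[r] <- "ND"; next }
    supp <- c(s1$position[c1], s2$position[c2])
    cen_dist[r] <- min(abs(supp - cen))
    l1 <- if (n1 >= 3) mean(f1[c1]) else NA_real_
    l2 <- if (n2 >= 3) mean(f2[c2]) else NA_real_
    comp[r] <- .region_composition(l1, l2, n1 / (n1 + n2), f, cn)
  }
  if (all(comp == "ND")) return("ND")
  # centromeric composition: the typed region whose supporting SNPs lie
  # nearest the centromere (regions are delimited by PCF breakpoints, and
  # SNP coverage around the centromere is sparse, so strict containment is
  # unreliable)
  typed <- which(comp != "ND")
  cen_comp <- comp[typed[which.min(cen_dist[typed])]]
  if (segmental || call$copy_state %in% c("loss", "neutral_UPD")) {
    if (any(comp == "BPH")) return("MI")   # meiotic material detected
    return("mitotic")
  }
  if (cen_comp == "BPH") return("MI")
  if (cen_comp == "SPH") {
    if (any(comp == "BPH")) return("MII")
    return("mitotic")
  }
  "ND"
}

#' Estimate maternal-cell contamination of a fetal sample
#'
#' Grid search (step 0.01) for the contamination fraction `c` maximizing
#' agreement between the observed BAF at parental-informative SNPs and the
#' `(1-c) * fetal + c * maternal-diploid` mixture expectation.  The fetal
#' expectation is kept phase-free (a contaminated seed genotype would bias
#' a CV-phased expectation toward the mixture itself): at a
#' maternal-informative SNP the euploid fetal BAF is 0 or 0.5 (father AA;
#' mirrored for BB) and the maternal contribution is 0.5, so the mixture
#' clusters sit at `{c/2, 0.5}`; at a paternal-informative SNP they sit at
#' `{0, (1-c)/2}` (mother AA; mirrored for BB).  Each SNP is scored
#' against its nearest admissible cluster, per chromosome, and the
#' chromosome estimates are combined by the median so that
#' single-chromosome aberrations do not bias the genome-wide value.  An
#' estimate above 0.95 with target genotype calls matching the maternal
#' ones is flagged as complete maternal contamination; such a sample is
#' excluded from calling.
#'
#' @param quartet a `"trio_quartet"`.
#' @param target `"CV"` or `"EM"`.
#' @param phase unused (kept for interface stability); the estimator is
#'   deliberately independent of the seed phase.
#' @return list: `c_hat`, `per_chromosome`, `complete_flag`, `concordance`,
#'   `note`.
#' @export
estimate_maternal_contamination <- function(quartet, target = c("CV", "EM"),
                                            phase = NULL) {
  target <- match.arg(target)
  if (target == "EM" && is.null(quartet$em)) stop("quartet has no EM sample")
  sample <- if (target == "CV") quartet$cv else quartet$em
  cat_ <- classify_informative_snps(quartet$mother$gtype,
                                    quartet$father$gtype)
  inf <- cat_ %in% c("paternal_informative", "maternal_informative")
  idx <- which(inf)
  mo <- .gt_dose(quartet$mother$gtype)[idx]
  fa <- .gt_dose(quartet$father$gtype)[idx]
  is_mat <- cat_[idx] == "maternal_informative"
  # orient every SNP so that the homozygous parent's allele is A
  hom_dose <- ifelse(is_mat, fa, mo)
  obs <- sample$baf[idx]
  obs <- ifelse(hom_dose == 2, 1 - obs, obs)
  grid <- seq(0, 1, 0.01)
  chrom <- quartet$probe_map$chromosome[idx]
  per_chrom <- vapply(split(seq_along(idx), chrom), function(i) {
    o <- obs[i]; m <- is_mat[i]
    # the two clusters are occupied about equally (Mendelian transmission),
    # so the lower quartile of the mat-informative BAF tracks the c/2
    # cluster and the upper quartile of the pat-informative BAF tracks the
    # (1-c)/2 cluster; matching quartiles is robust to the loss of one
    # cluster under complete contamination, where a nearest-cluster
    # distance would be uninformative
    q_mat <- stats::quantile(o[m], 0.25, na.rm = TRUE, names = FALSE)
    q_pat <- stats::quantile(o[!m], 0.75, na.rm = TRUE, names = FALSE)
    loss <- vapply(grid, function(cc) {
      l <- 0
      if (is.finite(q_mat)) l <- l + abs(q_mat - cc / 2)
      if (is.finite(q_pat)) l <- l + abs(q_pat - (1 - cc) / 2)
      l
    }, numeric(1))
    grid[which.min(loss)]
  }, numeric(1))
  c_hat <- stats::median(per_chrom)
  both <- sample$gtype != "NC" & quartet$mother$gtype != "NC"
  concordance <- mean(sample$gtype[both] == quartet$mother$gtype[both])
  complete <- c_hat > 0.95 && !is.na(concordance) && concordance > 0.99
  list(c_hat = c_hat, per_chromosome = per_chrom,
       complete_flag = complete, concordance = concordance,
       note = if (complete)
         "complete maternal contamination: target genotypes match the mother"
       else sprintf("grid-search estimate over %d chromosomes",
                    length(per_chrom)))
}

# per-interval Mendelian-inconsistency rates, by informative category
.fail_rates <- function(quartet, phase, chromosome, start, end) {
  pm <- quartet$probe_map
  rate <- function(cat) {
    sel <- function(ix) ix[pm$chromosome[ix] == chromosome &
                             pm$position[ix] >= start &
                             pm$position[ix] <= end]
    n <- length(sel(phase$informative_idx[[cat]]))
    nf <- length(sel(phase$fail_idx[[cat]]))
    if (n == 0) NA_real_ else nf / n
  }
  c(pat = rate("pat"), mat = rate("mat"))
}

# resolve the parental origin of a degenerate (f ~ 1) loss or UPD from the
# side of the Mendelian inconsistencies
.origin_from_fails <- function(state, fr, monosomy_origin = "lost") {
  hi <- 0.15; lo <- 0.05
  pick <- function(side) {
    if (state == "loss") {
      # fails concentrate among SNPs informative for the RETAINED parent
      lost <- if (side == "pat") "maternal" else "paternal"
      if (monosomy_origin == "lost") lost
      else if (lost == "maternal") "paternal" else "maternal"
    } else {
      # UPD: fails concentrate among SNPs informative for the disomic parent
      if (side == "pat") "paternal" else "maternal"
    }
  }
  p <- fr[["pat"]]; m <- fr[["mat"]]
  if (!is.na(p) && !is.na(m)) {
    if (p > hi && m < lo) return(pick("pat"))
    if (m > hi && p < lo) return(pick("mat"))
  }
  if (is.na(p) && !is.na(m)) {           # chromosome X: no paternal SNPs
    if (m > hi) return(pick("mat"))
    # without inconsistencies only a loss retaining the paternal X is
    # consistent; a UPD claim needs positive evidence
    if (state == "loss" && m < lo) return(pick("pat"))
  }
  "ND"
}

#' Call chromosomal aberrations in both tissues of a quartet
#'
#' End-to-end caller: seed phasing, contamination screening, haplarithm
#' construction, region partitioning along the PCF breakpoints, copy-state
#' and origin classification per region, mosaic-fraction estimation and
#' MI/MII/mitotic typing.  Calls with an estimated mosaic fraction below
#' `f_min` (default 0.10, the sensitivity floor of the method) are
#' suppressed.  When at least `min(20, autosomes on the scaffold)` autosomes
#' carry a consistent gain of the same parental origin, the calls are
#' labelled genome-wide (triploidy/tetrasomy signature).
#'
#' @param quartet a `"trio_quartet"`.
#' @param tissues tissues to call (default CV and EM when present).
#' @param gamma PCF penalty.
#' @param min_snps minimal informative SNPs per series per chromosome and
#'   per candidate region.
#' @param f_min mosaic-fraction floor below which calls are suppressed.
#' @param tol_d,tol_logr classification tolerances (see
#'   [classify_copy_state()]).
#' @param monosomy_origin labelling convention for monosomies: `"lost"`
#'   (default; the named parent is the one whose homolog is lost) or
#'   `"retained"`.
#' @param centromeres optional centromere table.
#' @param phase optional precomputed phase.
#' @param haplarithms optional named list of prebuilt haplarithms per
#'   tissue (avoids refitting when [haplarith()] drives the call).
#' @return data frame of class `"aberration_calls"`; attribute `excluded`
#'   lists tissues removed for complete maternal contamination.
#' @export
call_aberrations <- function(quartet, tissues = NULL, gamma = 14,
                             min_snps = 20, f_min = 0.10,
                             tol_d = 0.08, tol_logr = 0.15,
                             monosomy_origin = c("lost", "retained"),
                             centromeres = NULL, phase = NULL,
                             haplarithms = NULL) {
  monosomy_origin <- match.arg(monosomy_origin)
  if (is.null(tissues))
    tissues <- if (is.null(quartet$em)) "CV" else c("CV", "EM")
  if (is.null(phase)) phase <- phase_with_seed(quartet)
  if (is.null(centromeres)) centromeres <- centromere_positions()
  pm <- quartet$probe_map
  chroms <- intersect(.CHROMS, unique(pm$chromosome))
  n_autosomes <- sum(chroms != "X")
  gw_threshold <- min(20, n_autosomes)
  calls <- list()
  excluded <- character(0)
  for (tis in tissues) {
    contam <- estimate_maternal_contamination(quartet, tis, phase = phase)
    if (contam$complete_flag) { excluded <- c(excluded, tis); next }
    h <- if (!is.null(haplarithms) && !is.null(haplarithms[[tis]]))
      haplarithms[[tis]]
    else build_haplarithm(quartet, tis, gamma = gamma,
                          min_snps = min_snps, phase = phase)
    for (ch in chroms) {
      hc <- h$chromosomes[[ch]]
      pos_ch <- pm$position[pm$chromosome == ch]
      lo <- min(pos_ch); hi <- max(pos_ch)
      brk <- sort(unique(unlist(c(
        lapply(hc$series, .series_breaks),
        list(.series_breaks(list(segments = hc$logr_segments)))))))
      brk <- brk[brk > lo & brk < hi]
      bounds <- c(lo - 1, brk, hi)
      cells <- list()
      for (r in seq_len(length(bounds) - 1)) {
        a <- bounds[r] + 1; b <- bounds[r + 1]
        n_inf <- sum(vapply(hc$series, function(s)
          sum(s$position >= a & s$position <= b), numeric(1)))
        eligible <- (b - a + 1 >= 1e5) && (n_inf >= min_snps)
        cls <- NULL
        if (eligible) {
          dv <- compute_d_values(h, ch, a, b)
          cls <- classify_copy_state(dv, tol_d, tol_logr)
          cls$dv <- dv
        }
        cells[[r]] <- list(start = a, end = b, eligible = eligible,
                           cls = cls)
      }
      # merge consecutive same-signature cells, bridging ineligible/ND gaps
      # (copy number is not part of the key: a mosaic double gain at f/2 is
      # band-identical to a single gain at f, so CN assignment can flap
      # between adjacent cells)
      key <- vapply(cells, function(cl) {
        if (!cl$eligible || is.null(cl$cls)) return("skip")
        if (cl$cls$copy_state %in% c("disomy")) return("disomy")
        if (cl$cls$copy_state == "ND") return("skip")
        paste(cl$cls$copy_state, cl$cls$parental_origin)
      }, character(1))
      regions <- list(); cur <- NULL
      for (r in seq_along(cells)) {
        k <- key[r]
        if (k == "skip") next
        if (k == "disomy") { if (!is.null(cur)) { regions[[length(regions) + 1]] <- cur; cur <- NULL }; next }
        if (!is.null(cur) && cur$key == k) cur$end <- cells[[r]]$end
        else {
          if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
          cur <- list(key = k, start = cells[[r]]$start,
                      end = cells[[r]]$end)
        }
      }
      if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
      # a whole-chromosome aberration can come out fragmented (spurious
      # breakpoints from logR noise, plus cells individually slipping to a
      # neighbouring template); when the whole-chromosome classification
      # agrees with fragments that span most of the chromosome, consolidate
      # them into a single chromosomal region
      whole_cls <- classify_copy_state(compute_d_values(h, ch, lo, hi),
                                       tol_d, tol_logr)
      if (!whole_cls$copy_state %in% c("disomy", "ND") &&
          length(regions) > 0) {
        wk <- paste(whole_cls$copy_state, whole_cls$parental_origin)
        mt <- vapply(regions, function(r) r$key == wk, logical(1))
        if (any(mt)) {
          span <- (max(vapply(regions[mt], `[[`, numeric(1), "end")) -
                   min(vapply(regions[mt], `[[`, numeric(1), "start"))) /
                  (hi - lo + 1)
          if (span >= 0.8) {
            regions <- c(regions[!mt],
                         list(list(key = wk,
                                   start = min(vapply(regions[mt], `[[`,
                                                      numeric(1), "start")),
                                   end = max(vapply(regions[mt], `[[`,
                                                    numeric(1), "end")))))
          }
        }
      }
      for (rg in regions) {
        # when every assessable cell on the chromosome carries this
        # region's signature (the rest being too small to type), the
        # aberration is chromosome-wide
        if (all(key %in% c("skip", rg$key))) { rg$start <- lo; rg$end <- hi }
        dv <- compute_d_values(h, ch, rg$start, rg$end)
        cls <- classify_copy_state(dv, tol_d, tol_logr)
        if (cls$copy_state %in% c("disomy", "ND")) next
        origin <- cls$parental_origin
        fr <- .fail_rates(quartet, phase, ch, rg$start, rg$end)
        is_full <- !is.null(cls$variant) && !is.na(cls$variant) &&
          cls$variant == "full"
        # a copy-neutral or loss call resting on a single, collapsed d
        # component (the other series unmeasurable, e.g. chromosome X) is
        # as degenerate as the full templates
        if (!is_full && cls$copy_state %in% c("loss", "neutral_UPD") &&
            xor(is.na(dv$d_pat), is.na(dv$d_mat)) &&
            min(dv$d_pat, dv$d_mat, na.rm = TRUE) < 0.1)
          is_full <- TRUE
        if (is_full || origin == "ND")
          origin <- .origin_from_fails(cls$copy_state, fr, monosomy_origin)
        # a degenerate presentation is only credible with the corroborating
        # Mendelian-inconsistency pattern
        if (is_full && origin == "ND") next
        # mosaic fraction from the heterozygous band of the series
        # informative for the non-origin parent; degenerate full
        # aberrations fall back to logR / the template fraction below
        other_l2 <- if (origin == "maternal") dv$bands$P$l2
                    else if (origin == "paternal") dv$bands$M$l2
                    else NA_real_
        delta <- if (is.na(other_l2)) NA_real_ else
          min(0.4999, abs(other_l2 - 0.5))
        f_hat <- if (is_full) {
          if (cls$copy_state == "loss")
            min(1, max(0, 2 * (1 - 2^dv$mean_logr))) else 1
        } else if (!is.na(delta)) {
          estimate_mosaic_fraction(delta, cls$copy_state, cls$copy_number)
        } else cls$f
        if (is.na(f_hat)) f_hat <- cls$f
        if (!is.na(f_hat) && f_hat < f_min) next
        span_frac <- (rg$end - rg$start + 1) / (hi - lo + 1)
        size_class <- if (span_frac >= 0.9) "chromosomal" else "segmental"
        cl <- list(tissue = tis, chromosome = ch,
                   start = rg$start, end = rg$end,
                   size_class = size_class,
                   copy_state = cls$copy_state,
                   copy_number = cls$copy_number,
                   parental_origin = origin,
                   mosaic_fraction = f_hat,
                   d_pat = dv$d_pat, d_mat = dv$d_mat,
                   mean_logr = dv$mean_logr)
        cl$segregational_origin <- infer_segregational_origin(
          h, cl, centromeres)
        calls[[length(calls) + 1]] <- cl
      }
    }
  }
  out <- if (length(calls) == 0) {
    data.frame(tissue = character(), chromosome = character(),
               start = numeric(), end = numeric(),
               size_class = character(), copy_state = character(),
               copy_number = integer(), parental_origin = character(),
               segregational_origin = character(),
               mosaic_fraction = numeric(), d_pat = numeric(),
               d_mat = numeric(), mean_logr = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(calls, function(cl)
      data.frame(tissue = cl$tissue, chromosome = cl$chromosome,
                 start = cl$start, end = cl$end,
                 size_class = cl$size_class, copy_state = cl$copy_state,
                 copy_number = cl$copy_number,
                 parental_origin = cl$parental_origin,
                 segregational_origin = cl$segregational_origin,
                 mosaic_fraction = cl$mosaic_fraction,
                 d_pat = cl$d_pat, d_mat = cl$d_mat,
                 mean_logr = cl$mean_logr, stringsAsFactors = FALSE)))
  }
  # genome-wide signature: most autosomes carrying the same gain
  for (tis in tissues) {
    sel <- out$tissue == tis & out$copy_state == "gain" &
      out$size_class == "chromosomal" & out$chromosome != "X"
    for (org in c("maternal", "paternal")) {
      s2 <- sel & out$parental_origin == org
      if (sum(s2) >= gw_threshold) out$size_class[s2] <- "genome_wide"
    }
  }
  structure(out, excluded = excluded, class = c("aberration_calls",
                                                "data.frame"))
}
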