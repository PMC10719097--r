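# Synthetic quartet simulator: parental genomes, meioses with controlled
# segregation errors, conceptus assembly and array rendering.  The generator
# exists so that every downstream stage (phasing, segmentation,
# classification) can be exercised against known ground truth.

ABERRATION_TYPES <- c("none", "trisomy", "monosomy", "segmental_gain",
                      "segmental_loss", "upd_iso", "triploidy", "tetrasomy")
SEG_ORIGINS <- c("MI", "MII", "mitotic")

#' Describe a simulated chromosomal aberration
#'
#' @param type aberration type; one of `r paste(ABERRATION_TYPES, collapse=", ")`.
#' @param chromosome affected chromosome (ignored for `none` and `triploidy`).
#' @param start,end 1-based inclusive interval for segmental aberrations;
#'   segmental intervals must span at least 100 kb (the resolution floor of
#'   the method).  Whole-chromosome types must not carry an interval.
#' @param parent `"maternal"` or `"paternal"`.  For gains and UPD this is the
#'   parent contributing the abnormal number of copies; for monosomy it is,
#'   by the default labelling convention, the parent whose homolog is *lost*
#'   (see [call_aberrations()]).
#' @param seg_origin segregational origin: `"MI"`, `"MII"` or `"mitotic"`.
#'   Only trisomies (and triploidy, as `"MII"` second-polar-body retention or
#'   `"mitotic"` genome doubling) admit meiotic origins: a monosomy, an
#'   isodisomic UPD, a post-zygotic segmental event or a tetrasomy carries a
#'   single parental homolog throughout and is mitotic by construction.
#' @param mosaic_fraction_cv,mosaic_fraction_em fraction of aberrant cells in
#'   chorionic villi (CV) and extra-embryonic mesoderm (EM), in `[0, 1]`.
#' @return a list of class `"aberration_spec"`.
#' @export
aberration_spec <- function(type = "none", chromosome = NULL,
                            start = NULL, end = NULL,
                            parent = NULL, seg_origin = NULL,
                            mosaic_fraction_cv = 1,
                            mosaic_fraction_em = 1) {
  type <- match.arg(type, ABERRATION_TYPES)
  if (mosaic_fraction_cv < 0 || mosaic_fraction_cv > 1 ||
      mosaic_fraction_em < 0 || mosaic_fraction_em > 1)
    stop("mosaic fractions must lie in [0, 1]")
  if (type != "none") {
    if (type != "triploidy") {
      if (is.null(chromosome)) stop("chromosome required for type ", type)
      chromosome <- normalize_chrom(chromosome)
    }
    if (is.null(parent)) stop("parent_of_origin required for type ", type)
    parent <- match.arg(parent, c("maternal", "paternal"))
    if (is.null(seg_origin))
      seg_origin <- if (type == "trisomy") "MI" else
                    if (type == "triploidy") "MII" else "mitotic"
    seg_origin <- match.arg(seg_origin, SEG_ORIGINS)
    if (type %in% c("monosomy", "upd_iso", "segmental_gain",
                    "segmental_loss", "tetrasomy") && seg_origin != "mitotic")
      stop("type ", type, " carries a single parental homolog throughout; ",
           "only seg_origin = 'mitotic' is constructible")
    if (type == "triploidy" && seg_origin == "MI")
      stop("triploidy is simulated as MII (second polar body retention) or ",
           "mitotic (genome doubling)")
    if (type %in% c("segmental_gain", "segmental_loss")) {
      if (is.null(start) || is.null(end))
        stop("segmental aberrations need start and end")
      if (end - start + 1 < 1e5)
        stop("segmental aberrations must span at least 100 kb")
      if (start < 1 || end > chromosome_length(chromosome))
        stop("interval outside chromosome span")
    } else if (!is.null(start) || !is.null(end)) {
      stop("type ", type, " affects whole chromosomes; no interval allowed")
    }
  }
  structure(list(type = type, chromosome = chromosome,
                 start = start, end = end, parent = parent,
                 seg_origin = seg_origin,
                 mosaic_fraction_cv = mosaic_fraction_cv,
                 mosaic_fraction_em = mosaic_fraction_em),
            class = "aberration_spec")
}

#' Array noise model
#'
#' @param baf_sd standard deviation of additive Gaussian BAF noise (values
#'   clipped back to `[0, 1]`).
#' @param logr_sd standard deviation of additive Gaussian logR noise.
#' @param maternal_contamination fraction of maternal (diploid) DNA mixed
#'   into the fetal sample signal, in `[0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a list of class `"noise_model"`.
#' @export
noise_model <- function(baf_sd = 0.03, logr_sd = 0.10,
                        maternal_contamination = 0, seed = NULL) {
  if (baf_sd < 0 || logr_sd < 0) stop("noise sds must be >= 0")
  if (maternal_contamination < 0 || maternal_contamination > 1)
    stop("maternal_contamination must lie in [0, 1]")
  structure(list(baf_sd = baf_sd, logr_sd = logr_sd,
                 maternal_contamination = maternal_contamination,
                 seed = seed),
            class = "noise_model")
}

new_parental_genome <- function(haps, probe_map) {
  structure(haps, probe_map = probe_map, class = "parental_genome")
}

#' Simulate a pair of parental genomes
#'
#' Draws each allele independently as Bernoulli(`pop_baf`) per haplotype.
#' The mother carries two haplotypes everywhere; the father is hemizygous on
#' X (a single haplotype).
#'
#' @param probe_map a [probe_map()].
#' @param seed integer seed (`NULL`: current RNG state).
#' @return a list with elements `mother` and `father`, each a
#'   `"parental_genome"`: a per-chromosome list of 0/1 haplotype matrices
#'   (rows are homologs H1, H2).
#' @export
simulate_parent_haplotypes <- function(probe_map, seed = NULL) {
  if (!inherits(probe_map, "probe_map") || nrow(probe_map) == 0)
    stop("empty or invalid probe map")
  idx <- chrom_index(probe_map)
  with_seed(seed, {
    draw <- function(hemi_x) {
      haps <- lapply(names(idx), function(ch) {
        p <- probe_map$pop_baf[idx[[ch]]]
        k <- if (hemi_x && ch == "X") 1L else 2L
        m <- matrix(stats::rbinom(k * length(p), 1, rep(p, each = k)),
                    nrow = k)
        rownames(m) <- paste0("H", seq_len(k))
        m
      })
      names(haps) <- names(idx)
      new_parental_genome(haps, probe_map)
    }
    list(mother = draw(hemi_x = FALSE), father = draw(hemi_x = TRUE))
  })
}

# parity of the number of crossovers between the centromere and each probe
.xo_parity <- function(pos, crossovers, cen) {
  par <- integer(length(pos))
  for (x in crossovers) {
    hit <- if (x >= cen) (pos > x) else (pos < x)
    # crossover between centromere and probe: probe beyond x, away from cen
    hit <- hit & (if (x >= cen) pos > cen else pos < cen)
    par <- par + as.integer(hit)
  }
  par %% 2L
}

.chromatid <- function(H, pos, crossovers, cen, anchor, involved) {
  id <- rep(anchor, length(pos))
  if (length(crossovers) > 0 && any(involved)) {
    par <- .xo_parity(pos, crossovers[involved], cen)
    id <- ifelse(par == 1L, 3L - anchor, anchor)
  }
  H[cbind(id, seq_along(pos))]
}

#' Simulate the maternal or paternal meiosis for one chromosome
#'
#' Produces the transmitted chromatid(s) of one meiosis.  With `error =
#' "none"` a single recombinant homolog is returned.  With `error = "MI"`
#' two chromatids whose centromeric segments derive from *different*
#' parental homologs are returned (both homologs present at the centromere).
#' With `error = "MII"` two sister-derived chromatids sharing the centromeric
#' segment but differing distal to at least one crossover are returned.
#' Each crossover involves any given chromatid with probability 1/2
#' (two of the four chromatids of the bivalent take part in an exchange).
#'
#' @param parent a `"parental_genome"`.
#' @param chromosome chromosome label.
#' @param crossover_positions base-pair positions of crossovers on this
#'   chromosome (may be empty).
#' @param error `"none"`, `"MI"` or `"MII"`.  `"MII"` requires at least one
#'   crossover, otherwise the result would be indistinguishable from a
#'   mitotic duplication.
#' @param seed integer seed (`NULL`: current RNG state).
#' @param centromere centromere position; defaults to the built-in table.
#' @return list of one (error "none") or two transmitted homolog vectors.
#' @export
simulate_meiosis <- function(parent, chromosome, crossover_positions = numeric(),
                             error = c("none", "MI", "MII"), seed = NULL,
                             centromere = NULL) {
  error <- match.arg(error)
  chromosome <- normalize_chrom(chromosome)
  pm <- attr(parent, "probe_map")
  i <- which(pm$chromosome == chromosome)
  if (length(i) == 0) stop("chromosome not on the probe map")
  pos <- pm$position[i]
  H <- parent[[chromosome]]
  L <- chromosome_length(chromosome)
  if (any(crossover_positions < 1 | crossover_positions > L))
    stop("crossover positions outside chromosome span")
  if (nrow(H) == 1) {               # hemizygous (paternal X)
    if (error != "none") stop("meiotic error not supported on a hemizygous chromosome")
    return(list(H[1, ]))
  }
  if (error == "MII" && length(crossover_positions) == 0)
    stop("MII error requires at least one crossover on the chromosome ",
         "(otherwise indistinguishable from a mitotic duplication)")
  cen <- if (is.null(centromere)) centromere_positions(chromosome) else centromere
  nxo <- length(crossover_positions)
  with_seed(seed, {
    switch(error,
      none = {
        anchor <- sample(1:2, 1)
        inv <- stats::runif(nxo) < 0.5
        list(.chromatid(H, pos, crossover_positions, cen, anchor, inv))
      },
      MI = {
        inv1 <- stats::runif(nxo) < 0.5
        inv2 <- stats::runif(nxo) < 0.5
        list(.chromatid(H, pos, crossover_positions, cen, 1L, inv1),
             .chromatid(H, pos, crossover_positions, cen, 2L, inv2))
      },
      MII = {
        anchor <- sample(1:2, 1)
        inv1 <- stats::runif(nxo) < 0.5
        inv2 <- stats::runif(nxo) < 0.5
        if (all(inv1 == inv2)) {
          # sisters must differ distal to at least one exchange
          j <- which.min(abs(crossover_positions - cen))
          inv2[j] <- !inv2[j]
        }
        list(.chromatid(H, pos, crossover_positions, cen, anchor, inv1),
             .chromatid(H, pos, crossover_positions, cen, anchor, inv2))
      })
  })
}

.new_line <- function() list()

.add_track <- function(line, chrom, alleles, parent, presence = NULL) {
  if (is.null(presence)) presence <- rep(1L, length(alleles))
  tr <- line[[chrom]]
  if (is.null(tr))
    tr <- list(alleles = NULL, presence = NULL, parent = character())
  tr$alleles <- rbind(tr$alleles, alleles)
  tr$presence <- rbind(tr$presence, presence)
  tr$parent <- c(tr$parent, parent)
  line[[chrom]] <- tr
  line
}

#' Assemble conceptus cell lines from transmitted gametes
#'
#' Combines the per-chromosome gametes into a euploid cell line and, for
#' aberration types other than `"none"`, the aberrant cell line implied by
#' the [aberration_spec()].  Mitotic errors are modelled post-zygotically:
#' duplication or loss of an already-transmitted homolog, so a single
#' parental homolog (SPH) is present along the whole affected chromosome.
#' `upd_iso` duplicates the transmitted homolog of the named parent and
#' removes the other parent's homolog.
#'
#' @param maternal_gametes,paternal_gametes per-chromosome lists of gamete
#'   homolog vectors (as returned by [simulate_meiosis()]); two homologs on
#'   the affected chromosome(s) for meiotic trisomies/triploidy, one
#'   elsewhere.
#' @param spec an [aberration_spec()].
#' @param probe_map the shared [probe_map()].
#' @return list with elements `euploid` and (when an aberration is
#'   specified) `aberrant`: per-chromosome allele/presence track sets.
#' @export
assemble_conceptus <- function(maternal_gametes, paternal_gametes, spec,
                               probe_map) {
  stopifnot(inherits(spec, "aberration_spec"))
  chroms <- intersect(.CHROMS, unique(probe_map$chromosome))
  idx <- chrom_index(probe_map)
  need2 <- function(g, ch) {
    if (length(g[[ch]]) < 2)
      stop("spec requires two transmitted homologs from the ", spec$parent,
           " gamete on chromosome ", ch)
    g[[ch]]
  }
  euploid <- .new_line()
  for (ch in chroms) {
    euploid <- .add_track(euploid, ch, maternal_gametes[[ch]][[1]], "mat")
    euploid <- .add_track(euploid, ch, paternal_gametes[[ch]][[1]], "pat")
  }
  if (spec$type == "none")
    return(list(euploid = euploid))

  og <- if (spec$parent == "maternal") maternal_gametes else paternal_gametes
  other <- if (spec$parent == "maternal") paternal_gametes else maternal_gametes
  olab <- if (spec$parent == "maternal") "mat" else "pat"
  xlab <- if (spec$parent == "maternal") "pat" else "mat"
  aberrant <- .new_line()
  for (ch in chroms) {
    affected <- (spec$type == "triploidy") ||
      (!is.null(spec$chromosome) && ch == spec$chromosome)
    if (!affected) {
      aberrant <- .add_track(aberrant, ch, maternal_gametes[[ch]][[1]], "mat")
      aberrant <- .add_track(aberrant, ch, paternal_gametes[[ch]][[1]], "pat")
      next
    }
    pos <- probe_map$position[idx[[ch]]]
    switch(spec$type,
      trisomy = , triploidy = {
        if (spec$seg_origin == "mitotic" ||
            (spec$type == "triploidy" && length(og[[ch]]) < 2)) {
          # post-zygotic duplication of the transmitted homolog (also the
          # fallback for a hemizygous X in paternal triploidy)
          g <- og[[ch]][[1]]
          aberrant <- .add_track(aberrant, ch, g, olab)
          aberrant <- .add_track(aberrant, ch, g, olab)
        } else {
          g <- need2(og, ch)
          aberrant <- .add_track(aberrant, ch, g[[1]], olab)
          aberrant <- .add_track(aberrant, ch, g[[2]], olab)
        }
        aberrant <- .add_track(aberrant, ch, other[[ch]][[1]], xlab)
      },
      tetrasomy = {
        g <- og[[ch]][[1]]
        for (k in 1:3) aberrant <- .add_track(aberrant, ch, g, olab)
        aberrant <- .add_track(aberrant, ch, other[[ch]][[1]], xlab)
      },
      monosomy = {
        # parent_of_origin labels the LOST parent
        aberrant <- .add_track(aberrant, ch, other[[ch]][[1]], xlab)
      },
      upd_iso = {
        g <- og[[ch]][[1]]
        aberrant <- .add_track(aberrant, ch, g, olab)
        aberrant <- .add_track(aberrant, ch, g, olab)
      },
      segmental_gain = {
        inseg <- as.integer(pos >= spec$start & pos <= spec$end)
        aberrant <- .add_track(aberrant, ch, maternal_gametes[[ch]][[1]], "mat")
        aberrant <- .add_track(aberrant, ch, paternal_gametes[[ch]][[1]], "pat")
        aberrant <- .add_track(aberrant, ch, og[[ch]][[1]], olab,
                               presence = inseg)
      },
      segmental_loss = {
        inseg <- as.integer(!(pos >= spec$start & pos <= spec$end))
        if (spec$parent == "maternal") {
          aberrant <- .add_track(aberrant, ch, maternal_gametes[[ch]][[1]],
                                 "mat", presence = inseg)
          aberrant <- .add_track(aberrant, ch, paternal_gametes[[ch]][[1]], "pat")
        } else {
          aberrant <- .add_track(aberrant, ch, maternal_gametes[[ch]][[1]], "mat")
          aberrant <- .add_track(aberrant, ch, paternal_gametes[[ch]][[1]],
                                 "pat", presence = inseg)
        }
      })
  }
  list(euploid = euploid, aberrant = aberrant)
}

#' Genotype calls from noise-free BAF
#'
#' Cluster-style thresholds emulating array genotype calling: BAF < 0.15 is
#' AA, > 0.85 is BB, within `[0.25, 0.75]` AB, otherwise NC.  The AB band is
#' deliberately wide so that the 1/3 and 2/3 BAF clusters of a trisomic
#' sample are assigned to the heterozygous cluster, as array callers do.
#'
#' @param baf numeric vector of noise-free BAF values.
#' @return character vector of `AA`/`AB`/`BB`/`NC` calls.
#' @export
call_genotype <- function(baf) {
  out <- rep("NC", length(baf))
  out[!is.na(baf) & baf < 0.15] <- "AA"
  out[!is.na(baf) & baf > 0.85] <- "BB"
  out[!is.na(baf) & baf >= 0.25 & baf <= 0.75] <- "AB"
  out
}

new_sample_array <- function(gtype, baf, logr, role) {
  structure(data.frame(gtype = gtype, baf = baf, logr = logr,
                       stringsAsFactors = FALSE),
            sample_role = role, class = c("sample_array", "data.frame"))
}

#' Render a SNP array from cell lines
#'
#' Per SNP, BAF is the weighted B-allele copy count over the total weighted
#' copy count across cell lines, mixed with a maternal diploid signal at the
#' contamination fraction, then noised and clipped to `[0, 1]`.  logR is
#' log2(weighted mean copy number / 2) plus noise.  Genotype calls are
#' derived from the noise-free (but contaminated) BAF via
#' [call_genotype()].
#'
#' @param cell_lines list of cell lines (see [assemble_conceptus()]).
#' @param fractions per-line cell fractions; must lie in `[0, 1]` and sum
#'   to 1.
#' @param mother the maternal `"parental_genome"` (contamination source).
#' @param noise a [noise_model()].
#' @param probe_map the shared [probe_map()].
#' @param sample_role one of `"mother"`, `"father"`, `"CV"`, `"EM"`.
#' @return a `"sample_array"`: data frame with `gtype`, `baf`, `logr`.
#' @export
render_array <- function(cell_lines, fractions, mother, noise, probe_map,
                         sample_role = "CV") {
  if (any(fractions < 0 | fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must lie in [0, 1] and sum to 1")
  if (length(fractions) != length(cell_lines))
    stop("one fraction per cell line required")
  idx <- chrom_index(probe_map)
  n <- nrow(probe_map)
  B <- numeric(n); TOT <- numeric(n)
  for (k in seq_along(cell_lines)) {
    f <- fractions[k]
    if (f == 0) next
    for (ch in names(idx)) {
      tr <- cell_lines[[k]][[ch]]
      B[idx[[ch]]] <- B[idx[[ch]]] +
        f * colSums(tr$presence * tr$alleles)
      TOT[idx[[ch]]] <- TOT[idx[[ch]]] + f * colSums(tr$presence)
    }
  }
  cc <- noise$maternal_contamination
  if (cc > 0) {
    Bm <- numeric(n)
    for (ch in names(idx)) Bm[idx[[ch]]] <- colSums(mother[[ch]])
    B <- (1 - cc) * B + cc * Bm
    TOT <- (1 - cc) * TOT + cc * 2
  }
  baf0 <- ifelse(TOT > 0, B / TOT, NA_real_)
  logr0 <- ifelse(TOT > 0, log2(TOT / 2), NA_real_)
  gt <- call_genotype(baf0)
  with_seed(noise$seed, {
    baf <- pmin(1, pmax(0, baf0 + stats::rnorm(n, 0, noise$baf_sd)))
    logr <- logr0 + stats::rnorm(n, 0, noise$logr_sd)
    new_sample_array(gt, baf, logr, sample_role)
  })
}

# a parent's own array: the parental genome rendered as a single cell line
render_parent_array <- function(genome, noise, probe_map, sample_role) {
  line <- .new_line()
  for (ch in intersect(.CHROMS, unique(probe_map$chromosome))) {
    H <- genome[[ch]]
    for (r in seq_len(nrow(H)))
      line <- .add_track(line, ch, H[r, ],
                         if (sample_role == "mother") "mat" else "pat")
  }
  nm <- noise; nm$maternal_contamination <- 0
  render_array(list(line), 1, genome, nm, probe_map, sample_role)
}

new_trio_quartet <- function(probe_map, mother, father, cv, em = NULL,
                             truth = NULL) {
  n <- nrow(probe_map)
  for (s in list(mother, father, cv))
    if (nrow(s) != n) stop("sample track length must equal probe map length")
  if (!is.null(em) && nrow(em) != n)
    stop("sample track length must equal probe map length")
  structure(list(probe_map = probe_map, mother = mother, father = father,
                 cv = cv, em = em, truth = truth),
            class = "trio_quartet")
}

#' Simulate a full family quartet
#'
#' End-to-end generator: parental genomes, one maternal and one paternal
#' meiosis (with the segregation error demanded by `aberration`), conceptus
#' assembly, and rendering of the four arrays (mother, father, CV, EM).  CV
#' and EM derive from the same zygote and differ only in their aberrant-cell
#' fractions (and in their independent noise draws).
#'
#' @param aberration an [aberration_spec()].
#' @param probe_map a [probe_map()]; defaults to [default_probe_map()].
#' @param noise a [noise_model()]; its `seed` field is ignored here (the
#'   master `seed` governs all draws).
#' @param n_crossovers_per_arm crossovers per chromosome arm, at uniformly
#'   drawn positions.
#' @param seed master integer seed; every random draw derives from it.
#' @return a `"trio_quartet"` with a `truth` element recording the spec and
#'   the transmitted gametes.
#' @export
simulate_quartet <- function(aberration = aberration_spec(),
                             probe_map = default_probe_map(),
                             noise = noise_model(),
                             n_crossovers_per_arm = 1,
                             seed = 1) {
  stopifnot(inherits(aberration, "aberration_spec"))
  chroms <- intersect(.CHROMS, unique(probe_map$chromosome))
  with_seed(seed, {
    parents <- simulate_parent_haplotypes(probe_map)
    draw_xo <- function(ch) {
      cen <- centromere_positions(ch); L <- chromosome_length(ch)
      sort(c(stats::runif(n_crossovers_per_arm, 1, cen),
             stats::runif(n_crossovers_per_arm, cen, L)))
    }
    err_for <- function(parent_lab, ch) {
      if (is.null(aberration$parent) || aberration$parent != parent_lab)
        return("none")
      if (aberration$type == "trisomy" && ch == aberration$chromosome &&
          aberration$seg_origin %in% c("MI", "MII"))
        return(aberration$seg_origin)
      if (aberration$type == "triploidy" && aberration$seg_origin == "MII")
        return("MII")
      "none"
    }
    meiose <- function(genome, parent_lab) {
      g <- lapply(chroms, function(ch) {
        er <- err_for(parent_lab, ch)
        if (er == "MII" && nrow(genome[[ch]]) < 2) er <- "none"
        simulate_meiosis(genome, ch, draw_xo(ch), error = er)
      })
      names(g) <- chroms
      g
    }
    mg <- meiose(parents$mother, "maternal")
    pg <- meiose(parents$father, "paternal")
    lines <- assemble_conceptus(mg, pg, aberration, probe_map)
    frac <- function(f) {
      if (is.null(lines$aberrant)) list(lines["euploid"], 1)
      else list(lines, c(1 - f, f))
    }
    mk <- function(f, role) {
      fl <- frac(f)
      render_array(fl[[1]], fl[[2]], parents$mother, noise, probe_map, role)
    }
    qt <- new_trio_quartet(
      probe_map = probe_map,
      mother = render_parent_array(parents$mother, noise, probe_map, "mother"),
      father = render_parent_array(parents$father, noise, probe_map, "father"),
      cv = mk(aberration$mosaic_fraction_cv, "CV"),
      em = mk(aberration$mosaic_fraction_em, "EM"),
      truth = list(aberration = aberration, parents = parents,
                   maternal_gametes = mg, paternal_gametes = pg,
                   cell_lines = lines, noise = noise, seed = seed))
    qt
  })
}

#' @export
print.trio_quartet <- function(x, ...) {
  pm <- x$probe_map
  cat("Family quartet on", nrow(pm), "probes,",
      length(unique(pm$chromosome)), "chromosome(s)\n")
  cat("Samples: mother, father, CV",
      if (!is.null(x$em)) ", EM" else " (no EM)", "\n", sep = "")
  if (!is.null(x$truth)) {
    ab <- x$truth$aberration
    if (ab$type == "none") cat("Simulated ground truth: euploid\n")
    else cat(sprintf(
      "Simulated ground truth: %s chr%s (%s, %s), f_cv=%.2f f_em=%.2f\n",
      ab$type, if (is.null(ab$chromosome)) "ALL" else ab$chromosome,
      ab$parent, ab$seg_origin, ab$mosaic_fraction_cv, ab$mosaic_fraction_em))
  }
  invisible(x)
}
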