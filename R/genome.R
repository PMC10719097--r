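# Chromosome scaffold: GRCh37 chromosome lengths and centromere midpoints
# (cytoband p/q boundary), plus the ProbeMap container shared by all samples
# of a quartet.

.CHROMS <- c(as.character(1:22), "X")

.CHROM_INFO <- data.frame(
  chrom = .CHROMS,
  length = c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
    59128983, 63025520, 48129895, 51304566, 155270560),
  centromere = c(
    125.0e6, 93.3e6, 91.0e6, 50.4e6, 48.4e6, 61.0e6, 59.9e6, 45.6e6,
    49.0e6, 40.2e6, 53.7e6, 35.8e6, 17.9e6, 17.6e6, 19.0e6, 36.6e6,
    24.0e6, 17.2e6, 26.5e6, 27.5e6, 13.2e6, 14.7e6, 60.6e6),
  stringsAsFactors = FALSE
)

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix and keeps autosomes 1-22 and X.  Y is not a
#' supported chromosome (it carries no maternal haplarithm information and is
#' excluded from all statistics).
#'
#' @param x character or numeric vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  toupper(x)
}

#' Centromere coordinates
#'
#' Built-in per-chromosome centromere base-pair coordinates (GRCh37 cytoband
#' midpoints).  An alternative table can be loaded from a 3-column BED file
#' with [read_centromere_bed()].
#'
#' @param chromosomes chromosomes to return; default all supported.
#' @return named numeric vector of centromere positions (1-based bp).
#' @export
centromere_positions <- function(chromosomes = .CHROMS) {
  chromosomes <- normalize_chrom(chromosomes)
  bad <- setdiff(chromosomes, .CHROM_INFO$chrom)
  if (length(bad) > 0)
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  out <- .CHROM_INFO$centromere[match(chromosomes, .CHROM_INFO$chrom)]
  names(out) <- chromosomes
  out
}

#' Read centromere positions from a BED file
#'
#' Reads a 3+ column BED file (0-based half-open) of centromere intervals and
#' returns the interval midpoints as 1-based coordinates.
#'
#' @param path path to a BED file (`chrom`, `start`, `end`, ...).
#' @return named numeric vector as in [centromere_positions()].
#' @export
read_centromere_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file must have at least 3 columns")
  chrom <- normalize_chrom(tab[[1]])
  mid <- floor((as.numeric(tab[[2]]) + as.numeric(tab[[3]])) / 2) + 1
  pos <- vapply(split(mid, chrom), stats::median, numeric(1))
  pos[intersect(.CHROMS, names(pos))]
}

chromosome_length <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  .CHROM_INFO$length[match(chrom, .CHROM_INFO$chrom)]
}

#' Construct a probe map
#'
#' A probe map is the SNP scaffold shared by every sample of a quartet: probe
#' identifier, chromosome, 1-based position and population B-allele frequency.
#'
#' @param probe_id unique probe identifiers.
#' @param chromosome chromosome label per probe (1-22 or X).
#' @param position 1-based base-pair position, strictly increasing within each
#'   chromosome.
#' @param pop_baf population B-allele frequency in `[0, 1]`.
#' @return a `data.frame` of class `"probe_map"`.
#' @export
probe_map <- function(probe_id, chromosome, position, pop_baf) {
  chromosome <- normalize_chrom(chromosome)
  n <- length(probe_id)
  if (n == 0) stop("empty probe map")
  if (anyDuplicated(probe_id)) stop("probe ids must be unique")
  if (length(chromosome) != n || length(position) != n ||
      length(pop_baf) != n)
    stop("probe map columns must have equal length")
  if (any(!chromosome %in% .CHROMS))
    stop("unsupported chromosome label(s)")
  if (any(pop_baf < 0 | pop_baf > 1)) stop("pop_baf must lie in [0, 1]")
  pm <- data.frame(probe_id = as.character(probe_id),
                   chromosome = chromosome,
                   position = as.numeric(position),
                   pop_baf = as.numeric(pop_baf),
                   stringsAsFactors = FALSE)
  for (ch in unique(pm$chromosome)) {
    p <- pm$position[pm$chromosome == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Default simulated probe scaffold
#'
#' Draws a reduced-density SNP scaffold: `n_per_chrom` probes per chromosome
#' at uniform random positions, with population B-allele frequencies drawn
#' uniformly from `pop_baf_range`.  The default density (2,000 SNPs per
#' chromosome over 1-22 and X) keeps simulations at desk scale while
#' preserving sub-chromosomal (>100 kb) resolution.
#'
#' @param n_per_chrom number of probes per chromosome.
#' @param chromosomes chromosomes to include.
#' @param pop_baf_range range from which population BAFs are drawn.
#' @param seed integer seed for the scaffold draw.
#' @return a [probe_map()].
#' @export
default_probe_map <- function(n_per_chrom = 2000,
                              chromosomes = .CHROMS,
                              pop_baf_range = c(0.1, 0.9),
                              seed = 1) {
  chromosomes <- normalize_chrom(chromosomes)
  with_seed(seed, {
    pos <- lapply(chromosomes, function(ch) {
      L <- chromosome_length(ch)
      sort(sample.int(L - 2, n_per_chrom)) + 1
    })
    pm <- probe_map(
      probe_id = sprintf("snp_%s_%05d", rep(chromosomes, each = n_per_chrom),
                         rep(seq_len(n_per_chrom), length(chromosomes))),
      chromosome = rep(chromosomes, each = n_per_chrom),
      position = unlist(pos),
      pop_baf = stats::runif(n_per_chrom * length(chromosomes),
                             pop_baf_range[1], pop_baf_range[2]))
    pm
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  expr
}

# row indices of the probe map, by chromosome (in scaffold order)
chrom_index <- function(pm) {
  split(seq_len(nrow(pm)), factor(pm$chromosome, levels = .CHROMS),
        drop = TRUE)
}
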