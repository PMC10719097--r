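# Shared fixtures and independent oracles used across the test files.

# -- small scaffolds (built once per test run) -------------------------------

pm_six <- default_probe_map(800, chromosomes = as.character(1:6), seed = 3)
pm_three <- default_probe_map(2000, chromosomes = c("1", "2", "3"), seed = 2)

noise_free <- noise_model(baf_sd = 0, logr_sd = 0)

# a parent genome whose H1 is all-A and H2 all-B: gamete alleles then reveal
# homolog identity directly
hom_marked_parent <- function(pm) {
  haps <- lapply(split(seq_len(nrow(pm)), pm$chromosome), function(i)
    rbind(H1 = rep(0L, length(i)), H2 = rep(1L, length(i))))
  structure(haps, probe_map = pm, class = "parental_genome")
}

# -- exhaustive PCF oracle ---------------------------------------------------

# all segmentations of n points as breakpoint bitmasks, with the minimal
# penalized cost found by direct enumeration
pcf_oracle_tables <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    segs <- expand.grid(i = seq_len(n), j = seq_len(n))
    segs <- segs[segs$i <= segs$j, ]
    seg_id <- matrix(NA_integer_, n, n)
    seg_id[cbind(segs$i, segs$j)] <- seq_len(nrow(segs))
    masks <- 0:(2^(n - 1) - 1)
    A <- matrix(0, length(masks), nrow(segs))
    K <- integer(length(masks))
    for (m in seq_along(masks)) {
      brk <- which(bitwAnd(masks[m], 2^(0:(n - 2))) > 0)   # break after index
      ends <- c(brk, n); starts <- c(1, brk + 1)
      K[m] <- length(ends) - 1
      for (s in seq_along(ends)) A[m, seg_id[starts[s], ends[s]]] <- 1
    }
    out <- list(A = A, K = K, segs = segs, masks = masks)
    cache[[key]] <<- out
    out
  }
})

pcf_bruteforce <- function(y, gamma) {
  n <- length(y)
  tb <- pcf_oracle_tables(n)
  cs <- c(0, cumsum(y)); css <- c(0, cumsum(y^2))
  sse <- (css[tb$segs$j + 1] - css[tb$segs$i]) -
    (cs[tb$segs$j + 1] - cs[tb$segs$i])^2 / (tb$segs$j - tb$segs$i + 1)
  cost <- as.numeric(tb$A %*% sse) + gamma * tb$K
  b <- which.min(cost)
  brk <- which(bitwAnd(tb$masks[b], 2^(0:(n - 2))) > 0)
  list(cost = cost[b], ends = c(brk, n),
       gap = if (length(cost) > 1) sort(cost)[2] - cost[b] else Inf)
}

pcf_cost <- function(y, seg, gamma) {
  sum(vapply(seq_len(nrow(seg)), function(r) {
    v <- y[seg$start_idx[r]:seg$end_idx[r]]
    sum((v - mean(v))^2)
  }, numeric(1))) + gamma * (nrow(seg) - 1)
}

# -- allele-count enumeration oracle for rendered BAF ------------------------

# expected noise-free BAF/total-copy per probe, re-derived from the cell
# lines by direct counting (independent, loop-based path)
enumerate_bands <- function(cell_lines, fractions, pm,
                            mother = NULL, contamination = 0) {
  n <- nrow(pm)
  B <- numeric(n); TOT <- numeric(n)
  for (k in seq_along(cell_lines)) {
    line <- cell_lines[[k]]
    for (ch in names(line)) {
      i <- which(pm$chromosome == ch)
      tr <- line[[ch]]
      for (r in seq_along(tr$parent)) {
        B[i] <- B[i] + fractions[k] * tr$presence[r, ] * tr$alleles[r, ]
        TOT[i] <- TOT[i] + fractions[k] * tr$presence[r, ]
      }
    }
  }
  if (contamination > 0) {
    for (ch in unique(pm$chromosome)) {
      i <- which(pm$chromosome == ch)
      B[i] <- (1 - contamination) * B[i] +
        contamination * colSums(mother[[ch]])
      TOT[i] <- (1 - contamination) * TOT[i] + contamination * 2
    }
  }
  list(baf = ifelse(TOT > 0, B / TOT, NA_real_), total = TOT)
}

# -- aberration grid ---------------------------------------------------------

# every constructible combination of type x parent x segregational origin
grid_scenarios <- function() {
  out <- list()
  for (so in c("MI", "MII", "mitotic")) for (p in c("maternal", "paternal"))
    out[[length(out) + 1]] <- list(
      ab = aberration_spec("trisomy", "2", parent = p, seg_origin = so),
      state = "gain", parent = p, seg = so)
  for (p in c("maternal", "paternal")) {
    out[[length(out) + 1]] <- list(
      ab = aberration_spec("monosomy", "4", parent = p),
      state = "loss", parent = p, seg = "mitotic")
    out[[length(out) + 1]] <- list(
      ab = aberration_spec("upd_iso", "5", parent = p),
      state = "neutral_UPD", parent = p, seg = "mitotic")
    out[[length(out) + 1]] <- list(
      ab = aberration_spec("segmental_gain", "2", start = 6e7, end = 1.4e8,
                           parent = p),
      state = "gain", parent = p, seg = "mitotic")
    out[[length(out) + 1]] <- list(
      ab = aberration_spec("segmental_loss", "3", start = 4e7, end = 1.1e8,
                           parent = p),
      state = "loss", parent = p, seg = "mitotic")
  }
  out
}

run_grid_case <- function(sc, seed, pm = pm_six) {
  qt <- simulate_quartet(sc$ab, probe_map = pm, noise = noise_free,
                         seed = seed)
  calls <- haplarith(qt)$calls
  list(calls = calls,
       ok = nrow(calls) == 2 &&
         all(calls$copy_state == sc$state) &&
         all(calls$parental_origin == sc$parent) &&
         all(calls$segregational_origin == sc$seg) &&
         all(abs(calls$mosaic_fraction - 1) <= 0.05))
}

# -- exact rank-test enumeration oracles -------------------------------------

wsr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  ev <- n * (n + 1) / 4
  min(1, mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9))
}

mwu_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(nx + ny, nx)
  u_all <- apply(cmb, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  eu <- nx * ny / 2
  min(1, mean(abs(u_all - eu) >= abs(u_obs - eu) - 1e-9))
}

fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(support, r1, n - r1, c1)
  sum(pr[pr <= stats::dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
}
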