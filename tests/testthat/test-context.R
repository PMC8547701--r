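test_that("nearest gene distance uses the half-open gap, 0 on overlap", {
  tes <- tibble::tibble(copy_id = c("t1", "t2", "t3"), chrom = "chr1",
                        start = c(1000, 3500, 8000), end = c(2000, 4500, 9000))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(3000, 9000), end = c(4000, 9500))
  res <- nearest_gene_features(tes, genes)
  expect_equal(res$dist_gene[res$copy_id == "t1"], 1000)
  expect_equal(res$dist_gene[res$copy_id == "t2"], 0)
  expect_true(res$within_transcript[res$copy_id == "t2"])
  # adjacent intervals are at distance 0
  expect_equal(res$dist_gene[res$copy_id == "t3"], 0)
})

test_that("equidistant genes break leftmost-then-lexicographic", {
  tes <- tibble::tibble(copy_id = "t1", chrom = "chr1", start = 5000, end = 6000)
  genes <- tibble::tibble(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(7000, 3000), end = c(8000, 4000) # both 1000 bp away
  )
  res <- nearest_gene_features(tes, genes)
  expect_equal(res$closest_gene_id, "gA") # leftmost start wins
  same_start <- tibble::tibble(
    gene_id = c("gZ", "gA"), chrom = "chr1",
    start = c(7000, 7000), end = c(8000, 8000)
  )
  expect_equal(nearest_gene_features(tes, same_start)$closest_gene_id, "gA")
})

test_that("chromosomes without genes give missing distances, and the syntenic search is restricted", {
  tes <- tibble::tibble(copy_id = c("t1", "t2"), chrom = c("chr1", "chr2"),
                        start = c(0, 0), end = c(100, 100))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(500, 2000), end = c(600, 2100))
  res <- nearest_gene_features(tes, genes, syntenic_ids = "g2")
  expect_true(is.na(res$dist_gene[res$copy_id == "t2"]))
  expect_equal(res$closest_gene_id[res$copy_id == "t1"], "g1")
  expect_equal(res$closest_syntenic_gene_id[res$copy_id == "t1"], "g2")
  expect_equal(res$dist_syntenic_gene[res$copy_id == "t1"], 1900)
})

test_that("a linear genetic map is recovered exactly", {
  pts <- tibble::tibble(pos = seq(0, 1e6, by = 1e4), cM = seq(0, 1, length.out = 101))
  m <- fit_monotonic_map(pts)
  expect_equal(m$method, "polynomial")
  set.seed(31)
  s <- sort(sample.int(9e5, 20))
  rate <- te_recombination_rate(m, s, s + sample(1000:20000, 20, replace = TRUE))
  expect_equal(rate$cm_mb, rep(1.0, 20), tolerance = 1e-6)
  expect_false(any(rate$extrapolated))
  # clamped outside the fitted range and flagged
  out <- te_recombination_rate(m, 1e6 + 1000, 1e6 + 2000)
  expect_equal(out$cm_mb, 0)
  expect_true(out$extrapolated)
})

test_that("the fitted map is non-decreasing on a dense grid for random maps", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    pts <- tibble::tibble(
      pos = sort(sample.int(2e6, n)),
      cM = cumsum(rgamma(n, shape = 0.6, scale = 0.3))
    )
    m <- fit_monotonic_map(pts)
    grid <- seq(min(pts$pos), max(pts$pos), length.out = 5000)
    expect_true(all(diff(m$fn(grid)) >= -1e-12), info = paste("map", rep))
  }
})

test_that("a smooth quadratic map matches its analytic derivative", {
  # cM(x) = 2 * (x/L)^2 cM over L = 2 Mb: rate at interval [a, b] is
  # (cM(b) - cM(a)) / ((b - a)/1e6)
  L <- 2e6
  pts <- tibble::tibble(pos = seq(0, L, by = 2e4))
  pts$cM <- 2 * (pts$pos / L)^2
  m <- fit_monotonic_map(pts)
  a <- c(2e5, 8e5, 1.5e6); b <- a + 5e4
  analytic <- (2 * (b / L)^2 - 2 * (a / L)^2) / ((b - a) / 1e6)
  fitted <- te_recombination_rate(m, a, b)$cm_mb
  expect_equal(fitted, analytic, tolerance = 0.05)
})

test_that("sparse maps fall back to monotone piecewise-linear with warning", {
  pts <- tibble::tibble(pos = c(0, 5e5, 1e6), cM = c(0, 0.4, 1))
  expect_warning(m <- fit_monotonic_map(pts), "piecewise-linear")
  expect_equal(m$method, "piecewise_linear")
  expect_equal(m$fn(5e5), 0.4)
})

test_that("MNase counts and proportions match a per-base oracle", {
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  hs <- tibble::tibble(chrom = "chr1", start = 200, end = 210)
  res <- mnase_features(region, hs)
  expect_equal(res$mnase_count, 1)
  expect_equal(res$mnase_prop, 0.01)
  none <- mnase_features(region, tibble::tibble(chrom = "chr1", start = 5000, end = 5100))
  expect_equal(none$mnase_count, 0)
  expect_equal(none$mnase_prop, 0)

  set.seed(33)
  for (rep in 1:15) {
    reg <- tibble::tibble(chrom = "chr1", start = 100, end = 100 + sample(200:900, 1))
    k <- sample(1:8, 1)
    s <- sample.int(1200, k)
    hs <- tibble::tibble(chrom = "chr1", start = s, end = s + sample(10:100, k, replace = TRUE))
    got <- mnase_features(reg, hs)
    base_hit <- rep(FALSE, reg$end)
    n_int <- 0
    for (i in seq_len(k)) {
      span <- max(hs$start[i] + 1, reg$start + 1):min(hs$end[i], reg$end)
      if (hs$start[i] < reg$end && hs$end[i] > reg$start) {
        n_int <- n_int + 1
        base_hit[span] <- TRUE
      }
    }
    expect_equal(got$mnase_count, n_int)
    expect_equal(got$mnase_prop,
                 sum(base_hit[(reg$start + 1):reg$end]) / (reg$end - reg$start))
  }
})

test_that("segregating-site density counts positions inside the region", {
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  v <- tibble::tibble(chrom = "chr1", pos = c(5, 20, 40, 60, 80))
  expect_equal(segregating_site_density(region, v), 0.05)
  expect_equal(segregating_site_density(region, v[0, ]), 0)
  set.seed(34)
  for (rep in 1:15) {
    reg <- tibble::tibble(chrom = "chr1", start = 50, end = 50 + sample(50:500, 1))
    pos <- sort(sample.int(800, sample(5:50, 1)) - 1)
    vv <- tibble::tibble(chrom = "chr1", pos = pos)
    oracle <- sum(pos >= reg$start & pos < reg$end) / (reg$end - reg$start)
    expect_equal(segregating_site_density(reg, vv), oracle)
  }
})

test_that("subgenome assignment takes maximal overlap, ties to none", {
  sg <- tibble::tibble(
    chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
    subgenome = c("A", "B")
  )
  reg <- tibble::tibble(
    chrom = "chr1",
    start = c(100, 2500, 400, 500), end = c(600, 2600, 1400, 1500)
  )
  expect_equal(
    subgenome_assign(reg, sg),
    c("A", "none", "A", "none") # 600/400 bp split -> A; 500/500 tie -> none
  )
})

test_that("context features are invariant under coordinate translation", {
  shift <- 12345
  tes <- tibble::tibble(copy_id = "t1", chrom = "chr1", start = 2000, end = 3000)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 5000, end = 6000)
  hs <- tibble::tibble(chrom = "chr1", start = 2100, end = 2200)
  v <- tibble::tibble(chrom = "chr1", pos = c(2050, 2950, 4000))
  sg <- tibble::tibble(chrom = "chr1", start = 0, end = 10000, subgenome = "A")
  move <- function(df, cols) dplyr::mutate(df, dplyr::across(dplyr::all_of(cols), ~ .x + shift))

  expect_equal(
    nearest_gene_features(tes, genes)$dist_gene,
    nearest_gene_features(move(tes, c("start", "end")), move(genes, c("start", "end")))$dist_gene
  )
  expect_equal(
    mnase_features(tes, hs),
    mnase_features(move(tes, c("start", "end")), move(hs, c("start", "end")))
  )
  expect_equal(
    segregating_site_density(tes, v),
    segregating_site_density(move(tes, c("start", "end")), move(v, "pos"))
  )
  expect_equal(
    subgenome_assign(tes, sg),
    subgenome_assign(move(tes, c("start", "end")), move(sg, c("start", "end")))
  )
})
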