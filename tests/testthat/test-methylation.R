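# random per-cytosine call table over a small region
random_calls <- function(seed, n = 300, span = 2000,
                         tissues = c("leaf", "anther")) {
  set.seed(seed)
  tibble::tibble(
    chrom = "chr1",
    pos = sample.int(span, n, replace = TRUE) - 1L,
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    tissue = sample(tissues, n, replace = TRUE),
    methylated = runif(n) < 0.5
  )
}

test_that("window summaries aggregate counts into fixed 100 bp bins", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(105, 110, 120, 130, 140, 150, 160, 170, 180, 190),
    context = "CG", tissue = "leaf",
    methylated = c(rep(TRUE, 8), FALSE, FALSE)
  )
  w <- window_summarize(calls)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 100)
  expect_equal(w$total_c, 10)
  expect_equal(w$fraction, 0.8)
  expect_error(
    window_summarize(dplyr::mutate(calls, context = "CWW")),
    "unknown methylation context"
  )
  # pre-binned counts input: zero-coverage window is missing
  pre <- tibble::tibble(chrom = "chr1", pos = 0, context = "CG",
                        tissue = "leaf", methylated_c = 0, total_c = 0)
  expect_true(is.na(window_summarize(pre)$fraction))
})

test_that("window aggregation equals a brute-force group-by", {
  for (seed in 1:10) {
    calls <- random_calls(seed)
    w <- window_summarize(calls)
    oracle <- aggregate(
      cbind(m = calls$methylated, t = rep(1, nrow(calls))),
      by = list(
        start = floor(calls$pos / 100) * 100,
        context = calls$context, tissue = calls$tissue
      ), FUN = sum
    )
    joined <- merge(as.data.frame(w), oracle, by = c("start", "context", "tissue"))
    expect_equal(nrow(joined), nrow(w))
    expect_equal(joined$methylated_c, joined$m)
    expect_equal(joined$total_c, joined$t)
  }
})

test_that("body mean and 41-slot profile match a per-cytosine oracle", {
  # window-aligned TE so that window weighting is exact
  for (seed in 1:10) {
    calls <- random_calls(seed, n = 800, span = 6000)
    copies <- mk_copies("te1", "RLG00001", 2000, 2800)
    r <- resolve_nesting(copies)
    w <- window_summarize(calls)
    prof <- te_methylation_profile(r, w)
    for (ctx in c("CG", "CHG", "CHH")) {
      for (t in c("leaf", "anther")) {
        inside <- calls[calls$pos >= 2000 & calls$pos < 2800 &
                          calls$context == ctx & calls$tissue == t, ]
        body <- prof$value[prof$slot == 0 & prof$context == ctx & prof$tissue == t]
        if (nrow(inside) == 0) {
          expect_true(is.na(body))
        } else {
          expect_equal(body, mean(inside$methylated))
        }
        # 10th upstream flank window walks back from the TE start bin:
        # TE starts at 2000, so slot -10 is [1000, 1100)
        win <- calls[calls$pos >= 1000 & calls$pos < 1100 &
                       calls$context == ctx & calls$tissue == t, ]
        got <- prof$value[prof$slot == -10 & prof$context == ctx & prof$tissue == t]
        if (nrow(win) == 0) expect_true(is.na(got)) else expect_equal(got, mean(win$methylated))
      }
    }
    expect_equal(sum(prof$context == "CG" & prof$tissue == "leaf"), 41)
  }
})

test_that("body mean covers only owned segments of a disrupted copy", {
  # host [0, 1000) with child [300, 700): host body excludes the child bases
  copies <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 1000),
    mk_copies("B", "DTA00001", 300, 700)
  )
  r <- resolve_nesting(copies)
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(50, 150, 450, 550, 850, 950),
    context = "CG", tissue = "leaf",
    methylated = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  w <- window_summarize(calls)
  prof <- te_methylation_profile(r, w)
  a_body <- prof$value[prof$copy_id == "A" & prof$slot == 0]
  b_body <- prof$value[prof$copy_id == "B" & prof$slot == 0]
  expect_equal(a_body, 1.0) # child's unmethylated windows belong to B
  expect_equal(b_body, 0.0)
})

test_that("flanks beyond the chromosome ends are missing", {
  copies <- mk_copies("te1", "RLG00001", 0, 500) # flush with chromosome start
  r <- resolve_nesting(copies)
  calls <- random_calls(3, n = 200, span = 3000, tissues = "leaf")
  w <- window_summarize(calls)
  prof <- te_methylation_profile(r, w, chrom_lengths = c(chr1 = 1500))
  up <- prof[prof$slot < 0 & prof$context == "CG", ]
  expect_true(all(is.na(up$value)))
  # downstream windows beyond the 1500 bp chromosome end are missing too
  dn_far <- prof[prof$slot > 10 & prof$context == "CG", ]
  expect_true(all(is.na(dn_far$value)))
})

test_that("family-mean imputation fills gaps and preserves observed means", {
  copies <- mk_copies(
    c("a", "b", "c", "d"), c(rep("RLG00001", 3), "RLC00001"),
    c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500)
  )
  profiles <- tibble::tibble(
    copy_id = c("a", "b", "c", "d"), tissue = "leaf", context = "CG",
    slot = 0L, value = c(0.2, 0.4, NA, NA), imputed = FALSE
  )
  out <- impute_missing(profiles, copies)
  expect_equal(out$value[out$copy_id == "c"], 0.3) # family mean of {0.2, 0.4}
  expect_true(out$imputed[out$copy_id == "c"])
  expect_equal(out$value[out$copy_id == "a"], 0.2) # untouched
  expect_false(out$imputed[out$copy_id == "a"])
  # whole family missing -> superfamily (RL*) has no other member here, so
  # the global mean is used
  expect_equal(out$value[out$copy_id == "d"], 0.3)

  set.seed(41)
  for (rep in 1:10) {
    n <- 12
    cp <- mk_copies(sprintf("c%02d", 1:n),
                    sample(c("RLG00001", "RLG00002", "DTA00001"), n, replace = TRUE),
                    seq(0, by = 1000, length.out = n),
                    seq(0, by = 1000, length.out = n) + 500)
    pr <- tibble::tibble(
      copy_id = cp$copy_id, tissue = "leaf", context = "CG", slot = 0L,
      value = ifelse(runif(n) < 0.3, NA_real_, runif(n)), imputed = FALSE
    )
    imp <- impute_missing(pr, cp)
    pre <- pr %>%
      dplyr::left_join(cp[, c("copy_id", "family_id")], by = "copy_id") %>%
      dplyr::group_by(family_id) %>%
      dplyr::summarise(m = mean(value, na.rm = TRUE))
    post <- imp %>%
      dplyr::left_join(cp[, c("copy_id", "family_id")], by = "copy_id") %>%
      dplyr::group_by(family_id) %>%
      dplyr::summarise(m = mean(value))
    both <- dplyr::inner_join(pre, post, by = "family_id") %>%
      dplyr::filter(!is.nan(m.x))
    expect_equal(both$m.y, both$m.x, tolerance = 1e-12)
  }
})

test_that("TE bodies are more methylated than distant flanks in simulated data", {
  ds <- toy_dataset()
  r <- resolve_nesting(ds$te_copies)
  prof <- te_methylation_profile(
    r, ds$methylation,
    chrom_lengths = vapply(ds$genome, nchar, numeric(1))
  )
  cg <- prof[prof$context == "CG", ]
  body <- median(cg$value[cg$slot == 0], na.rm = TRUE)
  flank10 <- median(cg$value[abs(cg$slot) == 10], na.rm = TRUE)
  expect_gt(body, flank10)
})
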