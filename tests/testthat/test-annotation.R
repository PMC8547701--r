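test_that("GFF3 round trip converts coordinates and validates taxonomy", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttransposable_element\t101\t200\t.\t+\t.\tID=RLG00003_001;family=RLG00003;superfamily=RLG",
    "chr1\ttest\ttransposable_element\t500\t900\t.\t-\t.\tID=DTA00001_001;family=DTA00001;superfamily=DTA"
  ), gff)
  copies <- read_te_gff(gff)
  expect_equal(copies$start[1], 100)
  expect_equal(copies$end[1], 200)
  expect_equal(copies$end[1] - copies$start[1], 100)
  expect_equal(copies$order[copies$family_id == "RLG00003"], "LTR")
  expect_equal(copies$te_class[copies$family_id == "RLG00003"], "I")
  expect_equal(copies$order[copies$superfamily == "DTA"], "TIR")

  out <- tempfile(fileext = ".gff3")
  write_te_gff(copies, out)
  expect_equal(read_te_gff(out)[, names(copies)], copies)
})

test_that("GFF3 records with bad or missing taxonomy are rejected", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttransposable_element\t1\t100\t.\t+\t.\tID=x1;family=DTM99999;superfamily=RLC"
  ), gff)
  expect_error(read_te_gff(gff), "prefix does not match")

  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttransposable_element\t1\t100\t.\t+\t.\tID=x1;superfamily=RLC"
  ), gff)
  expect_error(read_te_gff(gff), "missing required attribute 'family'")
})

test_that("single nesting event splits the host and flags both copies", {
  copies <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 10000),
    mk_copies("B", "RLC00001", 4000, 5000, parents = "A")
  )
  r <- resolve_nesting(copies)
  a <- r$copies[r$copies$copy_id == "A", ]
  b <- r$copies[r$copies$copy_id == "B", ]
  expect_equal(a$surviving_bp, 9000)
  expect_equal(a$n_segments, 2)
  expect_true(a$disrupted)
  expect_false(a$within_te)
  expect_equal(b$surviving_bp, 1000)
  expect_true(b$within_te)
  expect_false(b$disrupted)
})

test_that("copies below the 50 bp survival threshold are dropped", {
  copies <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 100),
    mk_copies("B", "RLC00001", 10, 80)
  )
  r <- resolve_nesting(copies)
  expect_equal(r$copies$surviving_bp[r$copies$copy_id == "A"], 30)
  expect_true(r$copies$dropped[r$copies$copy_id == "A"])
  expect_false(r$copies$dropped[r$copies$copy_id == "B"])
})

test_that("a depth-3 chain assigns each base to the innermost copy", {
  copies <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 1000),
    mk_copies("B", "RLC00001", 100, 900),
    mk_copies("C", "RLX00001", 200, 300)
  )
  r <- resolve_nesting(copies)
  owner <- owner_vector_from_segments(copies, r$segments)
  expect_equal(copies$copy_id[owner[251]], "C") # base 250 (0-based)
  expect_equal(copies$copy_id[owner[151]], "B") # base 150
  expect_equal(copies$copy_id[owner[51]], "A") # base 50
  expect_equal(owner, per_base_ownership_oracle(copies))
})

test_that("resolution equals the per-base sweep oracle and conserves bases", {
  for (seed in 1:30) {
    copies <- random_nested_annotation(seed, genome_bp = 50000, n = 18)
    r <- resolve_nesting(copies)
    expect_equal(
      owner_vector_from_segments(copies, r$segments),
      per_base_ownership_oracle(copies),
      info = paste("seed", seed)
    )
    # conservation: owned bp (kept + dropped) equals union coverage
    cov <- sum(!is.na(per_base_ownership_oracle(copies)))
    expect_equal(sum(r$copies$surviving_bp), cov, info = paste("seed", seed))
  }
})

test_that("resolution without nesting returns whole single segments", {
  copies <- mk_copies(
    c("A", "B", "C"), rep("DTA00001", 3),
    c(0, 5000, 9000), c(1000, 6000, 9500)
  )
  r <- resolve_nesting(copies)
  expect_true(all(r$copies$n_segments == 1))
  expect_equal(r$copies$surviving_bp, r$copies$span_bp)
  expect_false(any(r$copies$disrupted | r$copies$within_te))
})

test_that("illegal annotations are rejected", {
  partial <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 1000),
    mk_copies("B", "RLC00001", 500, 1500)
  )
  expect_error(resolve_nesting(partial), "overlap without containment")

  bad_parent <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 1000),
    mk_copies("B", "RLC00001", 2000, 3000, parents = "A")
  )
  expect_error(resolve_nesting(bad_parent), "not contained in its declared parent")
})

test_that("autonomy rules follow superfamily-specific protein requirements", {
  copies <- mk_copies(
    c("r1", "r2", "r3", "t1", "h1", "l1", "s1"),
    c("RLG00001", "RLG00001", "RLG00002", "DTT00001", "DHH00001", "RIL00001", "RST00001"),
    seq(0, 60000, by = 10000), seq(0, 60000, by = 10000) + 5000
  )
  hits <- tibble::tibble(
    copy_id = c(rep("r1", 5), "r2", rep("r3", 4), "t1", "h1", "l1"),
    domain = c("GAG", "AP", "RT", "RNaseH", "INT", "GAG",
               "AP", "RT", "RNaseH", "INT", "TPase", "RepHel", "RT")
  )
  a <- classify_autonomy(copies, hits)
  get <- function(id, col) a[[col]][a$copy_id == id]
  expect_equal(get("r1", "status"), "autonomous_coding")
  expect_equal(get("r2", "status"), "partial_coding")
  expect_equal(get("r2", "partial_type"), "GAG_only")
  expect_equal(get("r3", "partial_type"), "POL_only")
  expect_equal(get("t1", "status"), "autonomous_coding")
  expect_equal(get("h1", "status"), "autonomous_coding")
  expect_equal(get("l1", "status"), "autonomous_coding")
  expect_equal(get("s1", "status"), "noncoding")
  expect_true(get("r2", "family_has_coding_member")) # r1 is coding, same family
  expect_false(get("r3", "family_has_coding_member"))
  expect_error(
    classify_autonomy(copies, tibble::tibble(copy_id = "r1", domain = "KRAB")),
    "unknown protein domain"
  )
})

test_that("family summaries: activity flag, histogram bins and medians", {
  copies <- mk_copies(
    c("a1", "a2", "b1"), c("RLG00001", "RLG00001", "DTA00001"),
    c(0, 10000, 20000), c(5000, 15000, 20400)
  )
  r <- resolve_nesting(copies)
  ages <- tibble::tibble(copy_id = c("a1", "a2", "b1"),
                         age_years = c(50e3, 2e5, 9e5))
  fs <- family_summary(r, ages)
  rlg <- fs[fs$family_id == "RLG00001", ]
  expect_true(rlg$active_last_100ky)
  expect_false(fs$active_last_100ky[fs$family_id == "DTA00001"])
  expect_equal(fs$copy_number[fs$family_id == "DTA00001"], 1)
  expect_equal(fs$prop_intact[fs$family_id == "DTA00001"], 1.0)

  h <- family_age_histogram(ages %>% dplyr::left_join(
    copies[, c("copy_id", "family_id")], by = "copy_id"
  ))
  expect_equal(sort(h$bin[h$family_id == "RLG00001"]), c(5, 20))

  # summary medians agree with a sort-based oracle on random fixtures
  sort_median <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(9)
  for (rep in 1:50) {
    k <- sample(3:9, 1)
    cp <- mk_copies(
      sprintf("c%02d", 1:k), rep("RLG00001", k),
      seq(0, by = 10000, length.out = k),
      seq(0, by = 10000, length.out = k) + sample(500:5000, k, replace = TRUE)
    )
    ag <- tibble::tibble(copy_id = cp$copy_id, age_years = runif(k, 0, 1e6))
    fs1 <- family_summary(resolve_nesting(cp), ag)
    expect_equal(fs1$median_age_years, sort_median(ag$age_years))
    expect_equal(fs1$median_length_bp, sort_median(cp$end - cp$start))
  }
})

test_that("families with no surviving copies are omitted with a warning", {
  copies <- dplyr::bind_rows(
    mk_copies("A", "RLG00001", 0, 100),
    mk_copies("B", "RLC00001", 10, 80) # A survives 30 bp -> dropped
  )
  r <- resolve_nesting(copies)
  ages <- tibble::tibble(copy_id = "B", age_years = 1e5)
  expect_warning(fs <- family_summary(r, ages), "no surviving copies")
  expect_false("RLG00001" %in% fs$family_id)
})
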