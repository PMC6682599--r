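test_that("top-3 quantification matches the sort-and-sum oracle", {
  # worked examples first
  rec <- make_records(c("AK", "CK", "DK", "EK"), "L1", c(10, 5, 3, 1))
  expect_equal(unname(as.matrix(top3_abundance(rec))[1, 1]),
               oracle_topn(c(10, 5, 3, 1)))   # 18
  rec <- make_records(c("AK", "CK"), "L1", c(7, 2))
  expect_equal(unname(as.matrix(top3_abundance(rec))[1, 1]),
               oracle_topn(c(7, 2)))          # 9
  # randomized cases
  set.seed(41)
  for (i in 1:60) {
    n <- sample(1:6, 1)
    areas <- round(runif(n, 0.1, 100), 3)
    rec <- make_records(paste0("PEP", LETTERS[1:n], "K"), "L1", areas)
    expect_equal(unname(as.matrix(top3_abundance(rec))[1, 1]),
                 oracle_topn(areas))
  }
})

test_that("modified and unmodified records of one peptide are pooled by sequence", {
  rec <- rbind(make_records("PEPSK", "L1", 4),
               make_records("PEPSK", "L1", 6, modifications = "4:Phospho"),
               make_records("OTHRK", "L1", 1))
  m <- as.matrix(top3_abundance(rec))
  expect_equal(unname(m[1, 1]), 11)   # (4 + 6) + 1
})

test_that("locations with no observations are missing; grid fixes the columns", {
  grid <- simulate_dataset(simulation_config(n_proteins = 2, seed = 1))$grid
  rec <- make_records("PEPK", "M3_r0_c0", 5)
  m <- as.matrix(top3_abundance(rec, grid))
  expect_equal(ncol(m), 21L)
  expect_equal(unname(m[1, "M3_r0_c0"]), 5)
  expect_true(all(is.na(m[1, colnames(m) != "M3_r0_c0"])))
})

test_that("adding a peptide observation never decreases a protein's abundance", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(1:6, 1)
    areas <- runif(n, 0, 50)
    rec <- make_records(paste0("PEP", LETTERS[1:n], "K"), "L1", areas)
    extra <- make_records("ZZNEWK", "L1", runif(1, 0, 50))
    before <- unname(as.matrix(top3_abundance(rec))[1, 1])
    after <- unname(as.matrix(top3_abundance(rbind(rec, extra)))[1, 1])
    expect_gte(after, before)
  }
})

test_that("rank-3 ties are resolved deterministically by sequence", {
  rec <- make_records(c("AAK", "BBK", "CCK", "DDK"), "L1", c(9, 5, 5, 5))
  m1 <- as.matrix(top3_abundance(rec))
  m2 <- as.matrix(top3_abundance(rec[c(4, 3, 2, 1), ]))
  expect_equal(m1, m2)
  expect_equal(unname(m1[1, 1]), 19)   # exactly three summands
})

test_that("volume normalization rescales by reference/volume", {
  grid <- data.frame(location_id = c("a", "b", "c"), tooth = "M3",
                     grid_row = 0:2, grid_col = 0, stage = "secretory",
                     volume_mm3 = c(2.14, 1.07, 4.28))
  m <- abundance_matrix(matrix(100, 1, 3, dimnames = list("P1", c("a", "b", "c"))),
                        "raw_area")
  vn <- as.matrix(volume_normalize(m, grid))
  expect_equal(unname(vn[1, ]), c(100, 200, 50))   # identity at 2.14 mm^3
  grid$volume_mm3[1] <- 0
  expect_error(volume_normalize(m, grid), class = "enamelmap_validation_error")
})

test_that("volume-normalized abundance scales linearly with peak area at fixed volume", {
  grid <- data.frame(location_id = "a", tooth = "M3", grid_row = 0,
                     grid_col = 0, stage = "secretory", volume_mm3 = 1.3)
  base <- matrix(runif(5, 1, 10), 5, 1,
                 dimnames = list(paste0("P", 1:5), "a"))
  v1 <- as.matrix(volume_normalize(abundance_matrix(base, "raw_area"), grid))
  v2 <- as.matrix(volume_normalize(abundance_matrix(base * 2, "raw_area"), grid))
  expect_equal(v2, v1 * 2)
})

test_that("percent scaling matches the arithmetic oracle and is idempotent", {
  m <- abundance_matrix(matrix(c(4, 2, NA), 1, 3,
                               dimnames = list("P1", c("a", "b", "c"))),
                        "raw_area")
  p <- as.matrix(percent_scale(m))
  expect_equal(unname(p[1, ]), c(100, 50, NA))
  const <- abundance_matrix(matrix(7, 2, 3, dimnames = list(c("P1", "P2"),
                                                            c("a", "b", "c"))),
                            "raw_area")
  expect_true(all(as.matrix(percent_scale(const)) == 100))
  single <- abundance_matrix(matrix(3, 1, 1, dimnames = list("P1", "a")),
                             "raw_area")
  expect_equal(unname(as.matrix(percent_scale(single))[1, 1]), 100)
  twice <- percent_scale(percent_scale(m))
  expect_equal(as.matrix(twice), as.matrix(percent_scale(m)))
})

test_that("zero-maximum and all-missing rows are dropped with an audit entry", {
  v <- matrix(c(0, 0, NA, NA, 5, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("zero", "gone", "ok"), c("a", "b")))
  p <- percent_scale(abundance_matrix(v, "raw_area"))
  expect_equal(rownames(as.matrix(p)), "ok")
  expect_setequal(p$audit$entity, c("zero", "gone"))
})

test_that("per-tooth percent scaling peaks at 100 within every tooth", {
  grid <- data.frame(location_id = c("a", "b", "c", "d"),
                     tooth = c("M3", "M3", "M2", "M2"), grid_row = 0,
                     grid_col = 0:3, stage = "secretory", volume_mm3 = 2)
  v <- matrix(c(8, 2, 1, 4), 1, 4, dimnames = list("P1", grid$location_id))
  p <- as.matrix(percent_scale(abundance_matrix(v, "raw_area"), grid))
  expect_equal(unname(p[1, ]), c(100, 25, 25, 100))
})

test_that("log transform maps 1 to 0, e to 1, zeros to audited missing, negatives to error", {
  v <- matrix(c(1, exp(1), 0), 1, 3,
              dimnames = list("P1", c("a", "b", "c")))
  lg <- log_transform(abundance_matrix(v, "raw_area"))
  expect_equal(unname(as.matrix(lg)[1, ]), c(0, 1, NA))
  expect_match(lg$audit$reason, "1 zero")
  vneg <- matrix(-1, 1, 1, dimnames = list("P1", "a"))
  expect_error(log_transform(vneg), class = "enamelmap_validation_error")
})

test_that("grid summary counts amount and diversity per location", {
  v <- matrix(c(5, NA), 1, 2, dimnames = list("P1", c("a", "b")))
  s <- summarize_grid(v)
  expect_equal(s$total_amount, c(5, 0))
  expect_equal(s$diversity, c(1L, 0L))
  s2 <- summarize_grid(rbind(v, v))
  expect_equal(s2$total_amount, 2 * s$total_amount)
  expect_equal(s2$diversity, 2L * s$diversity)
})

test_that("planted secretory-high simulation ranks secretory locations first in amount", {
  # plant uniformly secretory-high stage means and check the amount ranking
  n <- 40
  eff <- default_stage_effects(n, seed = 21)
  eff[, "secretory"] <- apply(eff, 1, max) + 1.5
  sim <- simulate_dataset(simulation_config(n_proteins = n, seed = 21,
                                            stage_effects = eff))
  flt <- filter_identifications(sim$peptides)
  vn <- volume_normalize(top3_abundance(flt$records, sim$grid), sim$grid)
  s <- summarize_grid(vn, sim$grid)
  n_secr <- sum(s$stage == "secretory")
  top <- s$stage[order(-s$total_amount)][seq_len(n_secr)]
  expect_true(all(top == "secretory"))
})

test_that("the canonical map pipeline order is fixed", {
  q <- quantified_simulation(seed = 2, n_proteins = 15)
  manual <- percent_scale(log_transform(volume_normalize(
    top3_abundance(q$filtered$records, q$sim$grid), q$sim$grid)))
  expect_equal(as.matrix(q$percent), as.matrix(manual))
  expect_identical(q$percent$scale, "percent")
})

test_that("abundance matrices round-trip through their TSV serialization", {
  q <- quantified_simulation(seed = 13, n_proteins = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(q$percent, path, seed = 13)
  back <- read_matrix_tsv(path)
  expect_equal(as.matrix(back), as.matrix(q$percent))
  expect_identical(back$scale, "percent")
})
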