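# Patient data model: GLSZM zone-size variance, synthetic cohort generation,
# CSV schema round-trip.

test_that("zone-size variance matches brute-force enumeration of zones", {
  # [[1,1],[1,1]]: four zones, sizes 1,1,2,2 -> mean 1.5, variance 0.25
  expect_equal(compute_zsv(matrix(c(1, 1, 1, 1), 2, 2)), 0.25)
  # brute force on an irregular matrix: replicate each (i, j) cell into
  # counts(i,j) zones of size j and take the population variance
  m <- matrix(c(2, 0, 1,
                0, 3, 1), nrow = 2, byrow = TRUE)
  sizes <- rep(rep(1:3, times = 2), times = as.integer(t(m)))
  expect_equal(compute_zsv(m), mean((sizes - mean(sizes))^2))
})

test_that("degenerate zone matrices have zero size variance", {
  expect_equal(compute_zsv(matrix(c(0, 4, 0, 0), 2, 2)), 0)
  one_col <- matrix(0, 4, 5)
  one_col[, 3] <- c(1, 2, 0, 7)
  expect_equal(compute_zsv(one_col), 0)
})

test_that("ZSV is invariant to zero padding and to the gray-level axis", {
  m <- matrix(c(1, 2, 0, 4, 0, 3), 2, 3)
  padded <- rbind(cbind(m, 0, 0), 0, 0)
  expect_equal(compute_zsv(padded), compute_zsv(m))
  # marginalizing gray levels first gives the same value
  expect_equal(compute_zsv(matrix(colSums(m), 1)), compute_zsv(m))
})

test_that("ZSV rejects invalid matrices and supports the printed variant", {
  expect_error(compute_zsv(matrix(0, 2, 2)), "positive")
  expect_error(compute_zsv(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
  m <- matrix(c(1, 1, 1, 1), 2, 2)
  p <- m / sum(m)
  j <- matrix(c(1, 1, 2, 2), 2, 2)
  jp <- j * p
  expect_equal(compute_zsv(m, normalization = "printed"),
               mean((jp - mean(jp))^2))
})

test_that("GLSZM round-trips through a dense CSV", {
  m <- matrix(c(0, 2, 5, 1, 0, 3), 2, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_glszm(path), m)
})

test_that("cohort generation is deterministic and supports n = 0", {
  cfg <- cohort_config(n_patients = 25L, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(generate_cohort(cohort_config(n_patients = 0L))), 0L)
  expect_error(cohort_config(n_patients = -1), class = "qdrlart_config_error")
  expect_error(cohort_config(genotype_freq = 1.4), class = "qdrlart_config_error")
  expect_error(cohort_config(t_lc = 2), class = "qdrlart_config_error")
})

test_that("synthetic outcome labels rise with dose and cover all classes", {
  co <- generate_cohort(cohort_config(n_patients = 2000L, seed = 5L))
  terc <- cut(co$clinical_dose,
              stats::quantile(co$clinical_dose, 0:3 / 3),
              include.lowest = TRUE)
  p_lc <- tapply(co$lc, terc, mean)
  p_rp2 <- tapply(co$rp2, terc, mean)
  expect_true(all(diff(p_lc) > 0))
  expect_true(all(diff(p_rp2) >= 0))
  expect_equal(sort(unique(paste(co$lc, co$rp2))),
               c("0 0", "0 1", "1 0", "1 1"))
})

test_that("cohort CSV write-read is an identity for every field", {
  co <- generate_cohort(cohort_config(n_patients = 3L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(back$genotype, co$genotype)
  expect_identical(back$lc, co$lc)
  expect_identical(back$rp2, co$rp2)
  expect_identical(back$patient_id, co$patient_id)
  for (cl in c("ip10_pre", "zsv_mid", "tumor_geud_mid", "clinical_dose")) {
    expect_equal(back[[cl]], co[[cl]], tolerance = 1e-12)
  }
})

test_that("schema violations are reported with the offending row", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")

  write_cohort(co, path)
  df <- utils::read.csv(path)
  df$rp2 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "rp2", class = "qdrlart_schema_error")

  bad <- co
  bad$lc[2] <- 2L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path), "row 2", class = "qdrlart_schema_error")

  bad <- co
  bad$clinical_dose[3] <- -1
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path), "row 3", class = "qdrlart_schema_error")
})
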