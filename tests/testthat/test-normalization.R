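test_that("normalisation divides by the adult mean and propagates missing", {
  idx <- connection_index()
  mk <- function(id, adult, r, keep = TRUE, pma = 40) {
    tibble::tibble(id = id, group = ifelse(adult, "adult", "40-42"),
                   pma = ifelse(adult, NA_real_, pma), adult = adult,
                   connection_id = idx$connection_id, r = r,
                   qc_keep = keep)
  }
  tab <- dplyr::bind_rows(
    mk("a1", TRUE, rep(0.2, 66)),
    mk("a2", TRUE, rep(0.4, 66)),
    mk("i1", FALSE, rep(0.15, 66))
  )
  ref <- adult_reference_means(tab)
  expect_equal(ref$r_ca, rep(0.3, 66))  # mean of (0.2, 0.4)
  normed <- normalize_connectome(tab, ref)
  expect_equal(normed$r_norm[normed$id == "i1"], rep(0.5, 66))  # 0.15 / 0.30
  # r = 0 maps to r_norm = 0; missing propagates
  tab2 <- dplyr::bind_rows(
    mk("a1", TRUE, rep(0.2, 66)), mk("a2", TRUE, rep(0.4, 66)),
    mk("i2", FALSE, rep(0, 66)),
    mk("i3", FALSE, rep(0.3, 66), keep = FALSE)
  )
  n2 <- normalize_connectome(tab2, adult_reference_means(tab2))
  expect_equal(n2$r_norm[n2$id == "i2"], rep(0, 66))
  expect_true(all(is.na(n2$r_norm[n2$id == "i3"])))
})

test_that("adults normalised by their own reference have mean r-norm exactly 1", {
  pc <- processed_small_cohort()
  normed <- normalize_connectome(pc$qc$table, pc$ref)
  ad_means <- dplyr::summarise(
    dplyr::group_by(normed[normed$adult & normed$qc_keep %in% TRUE, ],
                    connection_id),
    m = mean(r_norm), .groups = "drop")
  expect_equal(ad_means$m, rep(1, 66), tolerance = 1e-12)
})

test_that("a connection with no surviving adult values is an error", {
  pc <- processed_small_cohort()
  tab <- pc$qc$table
  tab$qc_keep[tab$adult & tab$connection_id == "thalamus-SI"] <- FALSE
  expect_error(adult_reference_means(tab), "thalamus-SI")
})

test_that("the presence threshold is the mean thalamus-SI r-norm of the youngest", {
  idx <- connection_index()
  mk <- function(id, pma, r_norm) {
    tibble::tibble(id = id, group = "<32", pma = pma, adult = FALSE,
                   connection_id = idx$connection_id, r = r_norm,
                   qc_keep = TRUE, r_norm = r_norm)
  }
  base <- rep(0.45, 66)
  t1 <- mk("i1", 29, ifelse(idx$connection_id == "thalamus-SI", 0.4, base))
  t2 <- mk("i2", 30, ifelse(idx$connection_id == "thalamus-SI", 0.6, base))
  pres <- presence_threshold(dplyr::bind_rows(t1, t2))
  expect_equal(pres$threshold, 0.5)
  out <- pres$table
  # 0.45 < 0.5 -> zeroed and absent
  expect_true(all(out$r_norm[out$connection_id != "thalamus-SI"] == 0))
  expect_true(all(!out$present[out$connection_id != "thalamus-SI"]))
  # the 0.6 value survives; 0.4 is below its own group mean and zeroed
  thal <- out[out$connection_id == "thalamus-SI", ]
  expect_equal(thal$r_norm[thal$id == "i2"], 0.6)
  expect_true(thal$present[thal$id == "i2"])
  expect_equal(thal$r_norm[thal$id == "i1"], 0)
})

test_that("values at exactly the threshold stay present", {
  idx <- connection_index()
  tab <- tibble::tibble(id = "i1", group = "<32", pma = 29, adult = FALSE,
                        connection_id = idx$connection_id,
                        r = 0.5, qc_keep = TRUE, r_norm = 0.5)
  pres <- presence_threshold(tab)
  expect_equal(pres$threshold, 0.5)
  expect_true(all(pres$table$r_norm == 0.5))
  expect_true(all(pres$table$present))
})

test_that("presence is monotone in r_norm", {
  pc <- processed_small_cohort()
  normed <- normalize_connectome(pc$qc$table, pc$ref)
  pres <- presence_threshold(normed)
  bumped <- normed
  nonref <- !(bumped$connection_id == "thalamus-SI" &
                !bumped$adult & !is.na(bumped$pma) & bumped$pma < 32)
  bumped$r_norm[nonref] <- bumped$r_norm[nonref] + 0.05
  pres2 <- presence_threshold(bumped)
  # identical threshold (reference values untouched), raised values: nothing
  # flips from present to absent
  expect_equal(pres2$threshold, pres$threshold)
  was_present <- pres$table$present %in% TRUE & nonref
  expect_true(all(pres2$table$present[was_present]))
})

test_that("QC must precede normalisation: permuting the stages changes results", {
  pc <- processed_small_cohort()
  # correct order: screen, then reference from survivors
  ref_correct <- pc$ref
  # permuted order: reference from unscreened values
  tab_noqc <- pc$qc$table
  tab_noqc$qc_keep <- TRUE
  ref_wrong <- adult_reference_means(tab_noqc)
  # inject one gross adult outlier to make the difference visible even when
  # the sampled cohort is clean
  tab2 <- pc$qc$table
  first_adult <- tab2$id[tab2$adult][1]
  sel <- tab2$adult & tab2$id == first_adult &
    tab2$connection_id == "OFC-dlPFC"
  tab2$r[sel] <- 0.9
  qc2 <- apply_outlier_qc(tab2[, setdiff(names(tab2), c("qc_keep", "qc_stat"))])
  ref_screened <- adult_reference_means(qc2$table)
  tab2_noqc <- qc2$table; tab2_noqc$qc_keep <- TRUE
  ref_unscreened <- adult_reference_means(tab2_noqc)
  cid <- "OFC-dlPFC"
  expect_false(isTRUE(all.equal(
    ref_screened$r_ca[ref_screened$connection_id == cid],
    ref_unscreened$r_ca[ref_unscreened$connection_id == cid])))
})

test_that("an empty reference group is an error", {
  idx <- connection_index()
  tab <- tibble::tibble(id = "a1", group = "adult", pma = NA_real_,
                        adult = TRUE, connection_id = idx$connection_id,
                        r = 0.3, qc_keep = TRUE, r_norm = 1)
  expect_error(presence_threshold(tab), "reference group")
})
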