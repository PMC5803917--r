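test_that("paired per-sample fold change matches closed forms", {
  design <- fix_design(n_pat = 3)
  base_ids <- design$sample_id[design$condition == "baseline"]
  trt_ids <- design$sample_id[design$condition == "treated"]
  gm <- tibble::tibble(gene = c("G1", "G2"))
  for (s in base_ids) gm[[s]] <- c(8, 2)
  for (s in trt_ids) gm[[s]] <- c(8, 8)   # G1 unchanged, G2 at 4x baseline
  fc <- fold_change(gm, design, arm = "BM")
  expect_equal(sort(unique(fc$column_id)), sort(trt_ids))  # one column per patient
  expect_equal(fc$log2fc[fc$gene == "G1"], rep(0, 3), tolerance = 1e-6)
  expect_equal(fc$log2fc[fc$gene == "G2"], rep(2, 3), tolerance = 1e-6)
})

test_that("unpaired treated samples are a design error naming the sample", {
  design <- fix_design(n_pat = 2)
  design <- design[design$sample_id != "PT2_BM_baseline", ]
  gm <- tibble::tibble(gene = "G1")
  for (s in design$sample_id) gm[[s]] <- 5
  expect_error(fold_change(gm, design, arm = "BM"), "PT2_BM_treated",
               class = "skinora_design_error")
})

test_that("swapping baseline and treated labels negates every fold change", {
  design <- fix_design(n_pat = 4)
  gm <- dplyr::rename(fix_values(sprintf("G%d", 1:30), design$sample_id,
                                 seed = 21), gene = probe_id)
  fc <- fold_change(gm, design, arm = "BM")
  flipped <- design
  flipped$condition <- ifelse(design$condition == "baseline",
                              "treated", "baseline")
  # pairing stays intact but the roles swap; column ids now are old baselines
  fc2 <- fold_change(gm, flipped, arm = "BM")
  key <- function(x) x[order(x$gene, x$column_id), ]
  m1 <- key(dplyr::mutate(tibble::as_tibble(fc),
                          column_id = sub("treated", "x", column_id)))
  m2 <- key(dplyr::mutate(tibble::as_tibble(fc2),
                          column_id = sub("baseline", "x", column_id)))
  expect_equal(m1$log2fc, -m2$log2fc, tolerance = 1e-12)
})

test_that("aggregate mode equals an independent median-of-groups recomputation", {
  design <- fix_design(n_pat = 5)
  gm <- dplyr::rename(fix_values(sprintf("G%d", 1:20), design$sample_id,
                                 seed = 9), gene = probe_id)
  fc <- fold_change(gm, design, arm = "BM", mode = "aggregate")
  expect_equal(unique(fc$column_id), "aggregate")

  sort_median <- function(x) {   # independent: explicit order statistics
    s <- sort(x); k <- length(s)
    if (k %% 2 == 1) s[(k + 1) / 2] else (s[k / 2] + s[k / 2 + 1]) / 2
  }
  base_ids <- design$sample_id[design$condition == "baseline"]
  trt_ids <- design$sample_id[design$condition == "treated"]
  manual <- vapply(seq_len(nrow(gm)), function(i) {
    log2(sort_median(unlist(gm[i, trt_ids])) + 1e-6) -
      log2(sort_median(unlist(gm[i, base_ids])) + 1e-6)
  }, numeric(1))
  expect_equal(fc$log2fc[match(gm$gene, fc$gene)], manual, tolerance = 1e-12)

  # treated medians exactly double baseline medians -> all-ones vector
  gm2 <- gm
  for (s in trt_ids) gm2[[s]] <- gm2[[sub("treated", "baseline", s)]] * 2
  fc2 <- fold_change(gm2, design, arm = "BM", mode = "aggregate")
  expect_equal(fc2$log2fc, rep(1, 20), tolerance = 1e-6)
})

test_that("genes with zero intensity in both conditions are excluded with a message", {
  design <- fix_design(n_pat = 1)
  gm <- tibble::tibble(gene = c("G1", "G2"),
                       PT1_BM_baseline = c(0, 4), PT1_BM_treated = c(0, 8))
  expect_message(fc <- fold_change(gm, design, arm = "BM"), "zero intensity")
  expect_equal(fc$gene, "G2")
  expect_true(all(is.finite(fc$log2fc)))
})

test_that("DEG calling includes the cutoff boundary with the printed signs", {
  fc <- fix_fc(c("UPX", "NEAR", "DOWNX", "FLAT"), "s1",
               c(1.0, 0.99, -1.7, 0.2))
  degs <- call_degs(fc, cutoff = 1.0)
  expect_equal(deg_genes(degs, "s1", "up"), "UPX")     # exactly +1.0 is up
  expect_equal(deg_genes(degs, "s1", "down"), "DOWNX")
  expect_false("NEAR" %in% degs$gene)                  # -0.99 / +0.99 is neither
  expect_error(call_degs(fc, cutoff = 0), class = "skinora_config_error")
})

test_that("DEG sets are nested in the cutoff and invariant to gene order", {
  withr::with_seed(13, {
    fc <- fix_fc(sprintf("G%03d", 1:200), "s1", rnorm(200, 0, 1))
  })
  d05 <- call_degs(fc, 0.5); d10 <- call_degs(fc, 1.0); d15 <- call_degs(fc, 1.5)
  expect_true(all(deg_genes(d15, "s1") %in% deg_genes(d10, "s1")))
  expect_true(all(deg_genes(d10, "s1") %in% deg_genes(d05, "s1")))

  shuffled <- fc[sample(nrow(fc)), ]
  expect_equal(sort(deg_genes(call_degs(shuffled, 1.0), "s1")),
               sort(deg_genes(d10, "s1")))
})
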