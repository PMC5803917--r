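test_that("median scaling brings every sample's median to exactly 1", {
  m <- tibble::tibble(probe_id = c("p1", "p2", "p3"), s1 = c(2, 4, 8))
  expect_equal(median_normalize(m)$s1, c(0.5, 1, 2))

  # two samples scaled independently (medians 4 and 10)
  m2 <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       s1 = c(2, 4, 8), s2 = c(5, 10, 20))
  out <- median_normalize(m2)
  expect_equal(median(out$s1), 1)
  expect_equal(median(out$s2), 1)
  expect_equal(out$s2, c(0.5, 1, 2))

  # already median-1 input is unchanged; idempotence on random data
  expect_equal(median_normalize(out), out)
  r <- fix_values(sprintf("p%d", 1:101), c("a", "b"), seed = 3)
  once <- median_normalize(r)
  expect_equal(median_normalize(once)$a, once$a, tolerance = 1e-12)
})

test_that("median scaling rejects unusable samples by name", {
  m <- tibble::tibble(probe_id = c("p1", "p2"), good = c(1, 2),
                      dead = c(0, 0))
  expect_error(median_normalize(m), "dead", class = "skinora_data_error")
  m$dead <- c(-1, 5)
  expect_error(median_normalize(m), "negative", class = "skinora_data_error")
})

test_that("detection filter boundary is inclusive at exactly 70%", {
  design <- fix_design(n_pat = 10)
  samples <- design$sample_id
  values <- fix_values(c("keep7", "drop6", "allA"), samples, seed = 5)
  calls <- fix_calls(values)
  base_ids <- design$sample_id[design$condition == "baseline"]
  trt_ids <- design$sample_id[design$condition == "treated"]
  # keep7: 7/10 P or M in both groups; drop6: 6/10 in the treated group only
  calls[calls$probe_id == "keep7", base_ids[1:3]] <- "A"
  calls[calls$probe_id == "keep7", trt_ids[1:2]] <- "A"
  calls[calls$probe_id == "keep7", trt_ids[3]] <- "M"
  calls[calls$probe_id == "drop6", trt_ids[1:4]] <- "A"
  calls[calls$probe_id == "allA", samples] <- "A"

  kept <- filter_by_detection(values, calls, design, threshold = 0.70)
  expect_equal(kept$probe_id, "keep7")

  # "any group" relaxation keeps the probe passing in one group
  kept_any <- filter_by_detection(values, calls, design, threshold = 0.70,
                                  group_rule = "any")
  expect_setequal(kept_any$probe_id, c("keep7", "drop6"))
})

test_that("detection filter is monotone in the threshold and validates it", {
  design <- fix_design(n_pat = 5)
  values <- fix_values(sprintf("p%02d", 1:40), design$sample_id, seed = 7)
  calls <- fix_calls(values)
  withr::with_seed(8, {
    flip <- matrix(runif(40 * nrow(design)) < 0.3, nrow = 40)
    for (j in seq_along(design$sample_id)) {
      calls[[design$sample_id[j]]][flip[, j]] <- "A"
    }
  })
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    nrow(filter_by_detection(values, calls, design, threshold = th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(filter_by_detection(values, calls, design, threshold = 0),
               class = "skinora_config_error")
  expect_error(filter_by_detection(values, calls, design, threshold = 1.2),
               class = "skinora_config_error")
})

test_that("probe collapse takes per-gene medians with the even-count convention", {
  values <- tibble::tibble(probe_id = c("a1", "a2", "a3", "b1", "b2", "x1"),
                           s1 = c(3, 5, 7, 3, 5, 99),
                           s2 = c(1, 2, 3, 10, 20, 99))
  map <- tibble::tibble(probe_id = c("a1", "a2", "a3", "b1", "b2"),
                        gene = c("ga", "ga", "ga", "gb", "gb"))
  expect_message(out <- collapse_probes(values, map), "1 probe")
  expect_equal(out$s1[out$gene == "GA"], 5)   # odd count: middle value
  expect_equal(out$s1[out$gene == "GB"], 4)   # even count: mean of middle two
  expect_equal(out$s2[out$gene == "GB"], 15)
  expect_false("X1" %in% out$gene)            # unmapped probe dropped
})

test_that("probe collapse demands one gene per probe and relabels 1:1 maps", {
  values <- fix_values(c("p1", "p2"), c("s1", "s2"), seed = 2)
  bad_map <- tibble::tibble(probe_id = c("p1", "p1"), gene = c("g1", "g2"))
  expect_error(collapse_probes(values, bad_map), "more than one gene",
               class = "skinora_data_error")

  map <- tibble::tibble(probe_id = c("p1", "p2"), gene = c("g1", "g2"))
  out <- collapse_probes(values, map)
  expect_equal(out$s1[match(c("G1", "G2"), out$gene)], values$s1)
  expect_equal(out$s2[match(c("G1", "G2"), out$gene)], values$s2)
})
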