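make_degs <- function(gene, column_id = "s1", columns = unique(column_id)) {
  structure(tibble::tibble(column_id = column_id, gene = gene),
            columns = columns, class = c("skinora_degs", "tbl_df",
                                         "tbl", "data.frame"))
}

test_that("up and down DEGs are pooled into one undirected DEG set", {
  kb <- fix_kb()
  degs_dir <- structure(
    tibble::tibble(column_id = "s1", gene = c("A", "D"),
                   direction = c("up", "down")),
    columns = "s1", class = c("skinora_degs", "tbl_df", "tbl", "data.frame"))
  degs_pool <- make_degs(c("A", "D"))
  expect_equal(tidy(enrich(degs_dir, kb))[, c("pathway", "a", "p_value")],
               tidy(enrich(degs_pool, kb))[, c("pathway", "a", "p_value")])
})

test_that("per-column enrichment covers every pathway with counts that add up", {
  kb <- fix_kb()
  res <- enrich(make_degs(c("A", "D")), kb)
  expect_equal(nrow(res), nrow(kb$pathways))
  expect_true(all(res$n == length(kb_universe(kb))))
  expect_true(all(res$a + res$b + res$c + res$d == res$n))
  p1 <- res[res$pathway == "P1", ]
  expect_equal(unlist(p1[, c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 2, d = 4), ignore_attr = TRUE)
})

test_that("a DEG set equal to one pathway's genes makes it the clear minimum p", {
  genes <- sprintf("G%04d", 1:2000)
  kb <- knowledge_base(tibble::tibble(
    pathway = c("target", sprintf("other%d", 1:9)),
    category = "x",
    genes = c(list(genes[1:20]),
              lapply(1:9, function(i) genes[20 + (i - 1) * 30 + 1:30]))))
  res <- enrich(make_degs(genes[1:20]), kb)
  expect_equal(res$pathway[which.min(res$p_value)], "target")
  expect_lt(min(res$p_value), 1e-20)
})

test_that("empty DEG sets yield p = 1 everywhere and no enrichment", {
  kb <- fix_kb()
  res <- enrich(make_degs(character(), column_id = character(),
                          columns = "s1"), kb)
  expect_equal(res$p_value, rep(1, nrow(kb$pathways)))
  expect_false(any(res$enriched))
})

test_that("the enriched flag uses a strict inequality", {
  kb <- fix_kb()
  res <- enrich(make_degs(c("A", "B", "C")), kb, alpha = 0)
  expect_false(any(res$enriched))
  # p = 1 rows are never enriched even at alpha = 1 (strict <)
  res2 <- enrich(make_degs(character(), column_id = character(),
                           columns = "s1"), kb, alpha = 1)
  expect_false(any(res2$enriched))
})

test_that("multi-column analysis keeps samples separate and summarises counts", {
  kb <- fix_kb()
  cols <- sprintf("s%d", 1:10)
  degs <- make_degs(rep(c("A", "B", "C"), 10),
                    column_id = rep(cols, each = 3), columns = cols)
  res <- enrich(degs, kb)
  summ <- enrichment_summary(res)
  expect_true(all(summ$n_enriched %in% c(0L, 10L)))  # identical DEG sets
  expect_equal(summ$n_columns, rep(10L, nrow(summ)))

  empty <- make_degs(character(), column_id = character(),
                     columns = character())
  expect_error(enrich(empty, kb), "at least one column",
               class = "skinora_data_error")
})

test_that("results are ordered by p then pathway name within each column", {
  kb <- fix_kb()
  res <- enrich(make_degs(c("A", "B", "C", "E")), kb)
  expect_false(is.unsorted(res$p_value))
  ties <- split(res$pathway, res$p_value)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("optional BH adjustment and measured-universe restriction work", {
  kb <- fix_kb()
  degs <- make_degs(c("A", "B", "C"))
  res <- enrich(degs, kb, adjust = "BH")
  expect_true(all(res$p_adjust >= res$p_value - 1e-15))
  expect_equal(res$enriched, res$p_adjust < 0.05)

  res_m <- enrich(degs, kb, universe = "kb_measured",
                  measured = c("A", "B", "C", "D"))
  expect_equal(unique(res_m$n), 4L)
  expect_error(enrich(degs, kb, universe = "kb_measured"),
               class = "skinora_config_error")
})

test_that("null DEG draws keep the significant fraction at or below nominal", {
  genes <- sprintf("G%04d", 1:500)
  kb <- knowledge_base(tibble::tibble(
    pathway = sprintf("PW%02d", 1:20), category = "x",
    genes = lapply(1:20, function(i) genes[(i - 1) * 25 + 1:25])))
  n_rep <- 80
  alpha <- 0.05
  withr::with_seed(123, {
    hits <- 0L; total <- 0L
    for (r in seq_len(n_rep)) {
      res <- enrich(make_degs(sample(genes, 15)), kb, alpha = alpha)
      hits <- hits + sum(res$p_value < alpha)
      total <- total + nrow(res)
    }
  })
  mc_err <- sqrt(alpha * (1 - alpha) / total)
  expect_lte(hits / total, alpha + 2 * mc_err)
})
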