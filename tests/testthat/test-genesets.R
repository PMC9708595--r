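test_that("constrained-gene selection uses a strict pLI threshold", {
  g <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      pli = c(0.95, 0.90, 0.10))
  expect_equal(select_pi(g)$gene_id, "g1")
  empty <- tibble::tibble(gene_id = character(), pli = numeric())
  expect_equal(nrow(select_pi(empty)), 0)
  all1 <- tibble::tibble(gene_id = c("a", "b"), pli = c(1, 1))
  expect_setequal(select_pi(all1)$gene_id, c("a", "b"))
})

test_that("raising the pLI threshold never adds members", {
  withr::with_seed(10, {
    g <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                        pli = runif(200))
    prev <- select_pi(g, 0)$gene_id
    for (thr in seq(0.1, 1, by = 0.1)) {
      cur <- select_pi(g, thr)$gene_id
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  })
})

test_that("top-expressed selection ranks by specificity with filtering", {
  # 5 genes, 5 cell types; focal type A has the stated expression while the
  # other four types each carry the stated other-type mean, so the
  # specificity denominator is the same under an all-type or other-type mean
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    A = c(10, 8, 1, 0, 5),
    B = c(1, 8, 1, 1, 1), C = c(1, 8, 1, 1, 1),
    D = c(1, 8, 1, 1, 1), E = c(1, 8, 1, 1, 1)
  )
  # grand means: g1 2.8, g2 8, g3 1, g4 0.8, g5 1.8 -> specificities
  # 10/2.81, 8/8.01, 1/1.01, (filtered), 5/1.81: g1 > g5 > g3 > g2
  top2 <- select_top_expressed(expr, "A", n = 2, min_expr = 0.5)
  expect_setequal(top2$gene_id, c("g1", "g5"))
  expect_equal(nrow(select_top_expressed(expr, "A", n = 0)), 0)
})

test_that("selection size is min(n, qualifying) when lenient, error when strict", {
  withr::with_seed(11, {
    expr <- sim_expression(sprintf("g%04d", 1:2500), 3, 0, seed = 12,
                           frac_unexpressed = 0.1)
  })
  n_qual <- sum(expr[[2]] >= 0.5)
  expect_gt(n_qual, 1600)
  got <- select_top_expressed(expr, names(expr)[2], n = 1600)
  expect_equal(nrow(got), 1600)
  expect_warning(
    short <- select_top_expressed(expr, names(expr)[2], n = n_qual + 10),
    "qualify"
  )
  expect_equal(nrow(short), n_qual)
  expect_error(
    select_top_expressed(expr, names(expr)[2], n = n_qual + 10,
                         strict = TRUE),
    "qualify"
  )
})

test_that("expression ties break lexicographically by gene id", {
  expr <- tibble::tibble(gene_id = c("gB", "gA", "gC"),
                         A = c(2, 2, 2), B = c(1, 1, 1))
  got <- select_top_expressed(expr, "A", n = 2, min_expr = 0)
  expect_setequal(got$gene_id, c("gA", "gB"))
})

test_that("homolog mapping drops unmapped and ambiguous members", {
  sets <- tibble::tibble(set = "m1", category = "mouse_cell",
                         gene_id = c("m_a", "m_b", "m_c", "m_amb"))
  map <- tibble::tibble(
    mouse_id = c("m_a", "m_b", "m_amb", "m_amb"),
    human_id = c("a", "b", "x", "y")
  )
  out <- map_homologs(sets, map)
  expect_setequal(out$gene_id, c("a", "b")) # m_c unmapped, m_amb ambiguous
  log <- attr(out, "homology_log")
  expect_equal(log$dropped_ambiguous, 1)
  expect_equal(log$dropped_unmapped, 1)

  bij <- tibble::tibble(mouse_id = c("m_a", "m_b", "m_c"),
                        human_id = c("a", "b", "c"))
  out2 <- map_homologs(sets[sets$gene_id != "m_amb", ], bij)
  expect_equal(nrow(out2), 3)
})

test_that("synaptic size filter is inclusive at the boundary", {
  raw <- dplyr::bind_rows(
    tibble::tibble(set = "s60", category = "synaptic",
                   gene_id = sprintf("a%02d", 1:60)),
    tibble::tibble(set = "s49", category = "synaptic",
                   gene_id = sprintf("b%02d", 1:49)),
    tibble::tibble(set = "s50", category = "synaptic",
                   gene_id = sprintf("c%02d", 1:50))
  )
  kept <- filter_synaptic(raw, min_size = 50)
  expect_setequal(unique(kept$set), c("s60", "s50"))
  expect_equal(nrow(filter_synaptic(raw[0, ])), 0)
  expect_setequal(unique(filter_synaptic(raw, min_size = 0)$set),
                  c("s60", "s49", "s50"))
})

test_that("intersections are subsets and preserve containment cases", {
  pi <- tibble::tibble(set = "PI", category = "PI",
                       gene_id = sprintf("g%02d", 1:20))
  contained <- tibble::tibble(set = "cellA", category = "human_cell",
                              gene_id = sprintf("g%02d", 5:10))
  disjoint <- tibble::tibble(set = "cellB", category = "human_cell",
                             gene_id = sprintf("h%02d", 1:6))
  expect_warning(
    inter <- intersect_pi(dplyr::bind_rows(contained, disjoint), pi),
    "empty intersection"
  )
  expect_setequal(set_members(inter, "cellA_x_PI"), contained$gene_id)
  expect_equal(length(set_members(inter, "cellB_x_PI")), 0)
  # the empty intersection is retained as an explicit flag, not silently lost
  expect_equal(attr(inter, "empty_sets"), "cellB_x_PI")

  # fuzzed subset property
  withr::with_seed(13, {
    for (i in 1:20) {
      uni <- sprintf("u%03d", 1:100)
      cs <- tibble::tibble(set = "c", category = "human_cell",
                           gene_id = sample(uni, sample(5:50, 1)))
      ps <- tibble::tibble(set = "PI", category = "PI",
                           gene_id = sample(uni, sample(5:50, 1)))
      ix <- suppressWarnings(intersect_pi(cs, ps))
      expect_lte(nrow(ix), min(nrow(cs), nrow(ps)))
      expect_true(all(ix$gene_id %in% cs$gene_id))
      expect_true(all(ix$gene_id %in% ps$gene_id))
    }
  })
})

test_that("background sets are nested by fraction", {
  withr::with_seed(14, {
    expr <- sim_expression(sprintf("g%04d", 1:1500), 3, 0, seed = 15,
                           frac_unexpressed = 0.2)
  })
  bg <- background_sets(expr)
  all_b <- set_members(bg, "brain_all")
  top50 <- set_members(bg, "brain_top50")
  top20 <- set_members(bg, "brain_top20")
  top10 <- set_members(bg, "brain_top10")
  expect_true(all(top10 %in% top20))
  expect_true(all(top20 %in% top50))
  expect_true(all(top50 %in% all_b))
  expect_equal(length(top10), floor(0.1 * length(all_b)))
  # exact fraction arithmetic on a round universe
  expr1000 <- expr[1:1000, ]
  expr1000[-1] <- expr1000[-1] + 1 # all expressed
  bg2 <- background_sets(expr1000, fractions = c(1, 0.1))
  expect_equal(length(set_members(bg2, "brain_all")), 1000)
  expect_equal(length(set_members(bg2, "brain_top10")), 100)
})

test_that("collection assembly counts categories and rejects duplicates", {
  mk <- function(names, category) {
    purrr::map_dfr(names, function(nm) {
      tibble::tibble(set = nm, category = category,
                     gene_id = paste0(nm, "_g", 1:3))
    })
  }
  pi <- mk("PI", "PI")
  human <- mk(sprintf("hum%02d", 1:14), "human_cell")
  mouse <- mk(sprintf("mus%02d", 1:24), "mouse_cell")
  syn <- mk(sprintf("syn%02d", 1:35), "synaptic")
  inter <- mk(paste0(c(sprintf("hum%02d", 1:14),
                       sprintf("mus%02d", 1:24)), "_x_PI"), "intersection")
  coll <- assemble_collection(pi, human, mouse, syn, inter)
  expect_equal(n_analysed_sets(coll), 112)

  only_pi <- assemble_collection(pi)
  expect_equal(n_analysed_sets(only_pi), 1)

  expect_error(assemble_collection(pi, mk("PI", "human_cell")),
               "duplicate")
  # backgrounds excluded from the analysed count
  bg <- mk("brain_all", "background")
  expect_equal(n_analysed_sets(assemble_collection(pi, background = bg)), 1)
})
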