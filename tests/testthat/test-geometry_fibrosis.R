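test_that("sheet and slab constructors validate their inputs", {
  g <- make_sheet(200, 200, 0.25)
  expect_equal(g$n_nodes, 40000L)
  expect_error(make_sheet(1, 5, 0.1), "nx and ny")
  expect_error(make_sheet(10, 10, 0), "dx")
  s <- make_slab(5, 6, 7, 0.3)
  expect_equal(s$n_nodes, 210L)
  expect_error(make_slab(5, 5, 2, 0.3), "nz")
})

test_that("every generator hits the exact fibrotic node count", {
  g <- tiny_sheet(60)
  for (amt in c(0.1, 0.25, 0.5)) {
    expect_equal(generate_diffuse(g, amt, 1)$n_fibrotic,
                 round(amt * g$n_nodes))
    expect_equal(generate_patchy(g, amt, 2)$n_fibrotic,
                 round(amt * g$n_nodes))
    expect_equal(generate_compact(g, amt, 3)$n_fibrotic,
                 round(amt * g$n_nodes))
  }
  expect_equal(sum(generate_diffuse(g, 0, 1)$labels), 0L)
  expect_equal(sum(generate_patchy(g, 0, 1)$labels), 0L)
  expect_error(generate_diffuse(g, 0.7, 1), "amount")
  expect_equal(generate_diffuse(g, 0.7, 1, allow_large = TRUE)$n_fibrotic,
               round(0.7 * g$n_nodes))
})

test_that("maps are fully determined by their seed", {
  g <- tiny_sheet(50)
  for (gen in list(generate_diffuse,
                   function(g, a, s) generate_patchy(g, a, s),
                   function(g, a, s) generate_compact(g, a, s))) {
    m1 <- gen(g, 0.2, 42)
    m2 <- gen(g, 0.2, 42)
    m3 <- gen(g, 0.2, 43)
    expect_identical(m1$labels, m2$labels)
    expect_false(identical(m1$labels, m3$labels))
  }
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_diffuse(g, 0.2, 7)); after <- runif(3)
  expect_identical(before, after)
})

test_that("patchy strands are elongated with embedded normal nodes", {
  g <- tiny_sheet(80)
  m <- generate_patchy(g, 0.3, 5)
  el <- fibroarrhythm:::component_elongation(m)
  expect_gte(mean(pmin(el, 50)), 3)
  # solid strands when gap_fill = 1: components have no interior holes,
  # checked as higher fibrotic fraction inside component bounding boxes
  m_solid <- generate_patchy(g, 0.15, 5, stripe_params = list(gap_fill = 1))
  m_gappy <- generate_patchy(g, 0.15, 5, stripe_params = list(gap_fill = 0.7))
  expect_equal(m_solid$n_fibrotic, m_gappy$n_fibrotic)
  expect_error(generate_patchy(g, 0.3, 1,
                               stripe_params = list(thickness = 10)),
               "length")
})

test_that("compact clusters are exactly n connected, flood-fill-complete components", {
  g <- tiny_sheet(60)
  m <- generate_compact(g, 0.1, 9, n_clusters = 3)
  comps <- fibroarrhythm:::fibrotic_components(m, "von_neumann")
  expect_length(comps, 3)
  expect_equal(sum(lengths(comps)), m$n_fibrotic)

  m1 <- generate_compact(g, 0.5, 10, n_clusters = 1)
  comps1 <- fibroarrhythm:::fibrotic_components(m1, "von_neumann")
  expect_length(comps1, 1)
  expect_equal(lengths(comps1)[[1]], round(0.5 * g$n_nodes))

  # independent connectivity oracle via igraph lattice components
  skip_if_not_installed("igraph")
  fib <- which(m$labels == 1L)
  nx <- g$nx
  x <- (fib - 1L) %% nx; y <- (fib - 1L) %/% nx
  fibset <- logical(g$n_nodes); fibset[fib] <- TRUE
  right <- fib[x < nx - 1L & fibset[pmin(fib + 1L, g$n_nodes)]]
  up <- fib[y < g$ny - 1L & fibset[pmin(fib + nx, g$n_nodes)]]
  e <- rbind(cbind(match(right, fib), match(right + 1L, fib)),
             cbind(match(up, fib), match(up + nx, fib)))
  gr <- igraph::make_empty_graph(n = length(fib), directed = FALSE)
  gr <- igraph::add_edges(gr, t(e))
  expect_equal(igraph::components(gr)$no, 3)
})

test_that("the study grid yields 75 deterministic configurations", {
  g <- tiny_sheet(40)
  ens <- generate_ensemble(g, base_seed = 123)
  expect_equal(nrow(ens$manifest), 75L)
  expect_length(ens$maps, 75L)
  expect_equal(sort(unique(ens$manifest$amount)), seq(0.1, 0.5, 0.1))
  expect_equal(unname(table(ens$manifest$pattern)), rep(25L, 3),
               ignore_attr = TRUE)
  ens2 <- generate_ensemble(g, base_seed = 123)
  expect_identical(ens$manifest, ens2$manifest)

  one <- generate_ensemble(g, patterns = "diffuse", amounts = 0.2,
                           n_replicates = 1, base_seed = 5)
  expect_equal(nrow(one$manifest), 1L)
})
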