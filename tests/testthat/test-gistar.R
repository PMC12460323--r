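test_that("Gi* matches direct per-unit formula evaluation", {
  W <- make_grid_weights(6, 8, "rook")
  x <- as.numeric(simulate_sar_field(W, 0.6, 1, seed = 21))
  g <- getis_ord_gistar(cross_section(W$unit_ids, x), W)
  M <- weights_matrix(W); diag(M) <- 1
  for (i in c(1, 17, 30, 48))
    expect_equal(g$z[i], gistar_bruteforce_one(x, M[i, ]),
                 tolerance = 1e-12)
})

test_that("a planted high block is the maximal-z hot spot at the 99% level", {
  W <- make_grid_weights(6, 8, "rook")
  x <- rep(0, 48)
  names(x) <- W$unit_ids
  block <- c("r2c2", "r2c3", "r3c2", "r3c3", "r1c2", "r1c3", "r2c1",
             "r3c1", "r2c4", "r3c4", "r4c2", "r4c3")
  x[block] <- 5
  g <- getis_ord_gistar(cross_section(names(x), as.numeric(x)), W)
  top <- g$unit[order(-g$z)][1:4]
  expect_true(all(top %in% block))
  expect_true(any(g$bin[match(top, g$unit)] == "hot99"))
  expect_true(all(g$z[match(c("r2c2", "r2c3", "r3c2", "r3c3"), g$unit)] >
                    2.576))
})

test_that("Gi* is antisymmetric under negation with swapped bins", {
  W <- make_grid_weights(5, 6, "rook")
  x <- as.numeric(simulate_sar_field(W, 0.7, 1, seed = 8))
  g1 <- getis_ord_gistar(cross_section(W$unit_ids, x), W)
  g2 <- getis_ord_gistar(cross_section(W$unit_ids, -x), W)
  expect_equal(g2$z, -g1$z, tolerance = 1e-12)
  swap <- c(hot99 = "cold99", hot95 = "cold95", hot90 = "cold90",
            ns = "ns", cold90 = "hot90", cold95 = "hot95",
            cold99 = "hot99")
  expect_equal(as.character(g2$bin),
               unname(swap[as.character(g1$bin)]))
})

test_that("Gi* is invariant under positive affine transforms", {
  W <- make_grid_weights(4, 5, "rook")
  x <- as.numeric(simulate_sar_field(W, 0.5, 1, seed = 30))
  g1 <- getis_ord_gistar(cross_section(W$unit_ids, x), W)
  g2 <- getis_ord_gistar(cross_section(W$unit_ids, 2.5 * x + 7), W)
  expect_equal(g1$z, g2$z, tolerance = 1e-10)
})

test_that("complete graph yields all-zero z (no local contrast)", {
  n <- 6
  ids <- letters[1:n]
  nbrs <- lapply(seq_len(n), function(i) ids[-i])
  W <- spatial_weights(ids, nbrs)
  g <- getis_ord_gistar(cross_section(ids, rnorm(n)), W)
  expect_equal(g$z, rep(0, n), tolerance = 1e-12)
  expect_true(all(g$bin == "ns"))
})

test_that("bin thresholds 1.645/1.960/2.576 are honored exactly", {
  z <- c(-3, -2.2, -1.7, -1, 0, 1.7, 2.2, 3, 1.645, -2.576)
  bins <- spatioepi:::gistar_bins(z)
  expect_equal(as.character(bins),
               c("cold99", "cold95", "cold90", "ns", "ns", "hot90",
                 "hot95", "hot99", "hot90", "cold99"))
})

test_that("hotspot persistence counts windows per confidence class", {
  W <- make_grid_weights(6, 8, "rook")
  # persistent elevated block across six windows
  x_base <- rep(0, 48); names(x_base) <- W$unit_ids
  block <- c("r2c2", "r2c3", "r3c2", "r3c3")
  halo <- c("r1c2", "r1c3", "r2c1", "r3c1", "r2c4", "r3c4", "r4c2",
            "r4c3")
  secs <- lapply(1:6, function(w) {
    set.seed(w)
    x <- x_base + rnorm(48, 0, 0.3)
    x[c(block, halo)] <- x[c(block, halo)] + 4
    g <- getis_ord_gistar(cross_section(names(x), as.numeric(x)), W)
    attr(g, "label") <- sprintf("w%d", w)
    g
  })
  per <- hotspot_persistence(secs)
  core <- per[per$unit %in% block, ]
  expect_true(all(core$n_hot >= 5))

  # alternating field: no unit persistent at any class
  cb <- checkerboard_field(W)
  alt <- lapply(1:4, function(w) {
    g <- getis_ord_gistar(cross_section(W$unit_ids,
                                        as.numeric(cb) * (-1)^w), W)
    attr(g, "label") <- sprintf("a%d", w)
    g
  })
  pa <- hotspot_persistence(alt)
  expect_true(all(pa$n_hot < 4 & pa$n_cold < 4))

  # mismatched unit sets error
  bad <- secs[[1]][-1, ]
  expect_error(hotspot_persistence(list(secs[[1]], bad)), "differ")
})
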