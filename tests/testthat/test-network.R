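# Structured random connectivity: layout, sampling, collaterals, composition,
# serialization.

test_that("default layout has the published compartment sizes", {
  lay <- network_layout()
  expect_equal(attr(lay, "n_total"), 500L)
  get_n <- function(pop, reg) lay$n[lay$population == pop & lay$region == reg]
  expect_equal(get_n("PY", "focal"), 40L)
  expect_equal(get_n("IN", "focal"), 10L)
  expect_equal(get_n("TC", "focal"), 40L)
  expect_equal(get_n("RE", "focal"), 40L)
  expect_equal(get_n("PY", "surrounding"), 160L)
  expect_equal(get_n("IN", "surrounding"), 40L)
  expect_equal(get_n("TC", "surrounding"), 80L)
  expect_equal(get_n("RE", "surrounding"), 80L)
  expect_equal(get_n("NT", "external"), 10L)
  # population totals: 200 PY + 50 IN + 120 TC + 120 RE + 10 NT
  tot <- tapply(lay$n, lay$population, sum)
  expect_equal(as.vector(tot[c("PY", "IN", "TC", "RE", "NT")]),
               c(200L, 50L, 120L, 120L, 10L))
  # index ranges tile [1, 500] without overlap
  ix <- unlist(lapply(seq_len(nrow(lay)),
                      function(r) seq.int(lay$first[r], lay$last[r])))
  expect_equal(sort(ix), 1:500)
})

test_that("probability table matches the published values and region ordering", {
  p <- coupling_probabilities()
  look <- function(t, s, reg) swdnet:::lookup_probability(p, t, s, reg)
  expect_equal(look("PY", "PY", "focal"), 0.036)
  expect_equal(look("PY", "IN", "focal"), 0.126)
  expect_equal(look("TC", "NT", "focal"), 0.18)
  expect_equal(look("TC", "NT", "surrounding"), 0)
  expect_equal(look("RE", "TC", "surrounding"), 0.0225)
  # pairs absent from the table get probability zero
  expect_equal(look("PY", "RE", "focal"), 0)
  expect_equal(look("NT", "PY", "focal"), 0)
  # focal probabilities dominate surrounding ones for every defined pair
  expect_true(all(p$focal >= p$surrounding))
})

test_that("sampling respects probabilities, signs, and determinism", {
  lay <- network_layout("focal")
  # all probabilities zero -> zero matrix
  p0 <- coupling_probabilities()
  p0$focal <- 0; p0$surrounding <- 0
  m0 <- sample_matrix(lay, p0, tau_steps = 9, seed = 1)
  expect_equal(length(m0$C@x), 0L)
  # saturation: probability 1 for PY<-PY focal, zero elsewhere
  p1 <- p0
  p1$focal[p1$target == "PY" & p1$source == "PY"] <- 1
  m1 <- sample_matrix(lay, p1, tau_steps = 9, seed = 1)
  py <- layout_indices(lay, "PY", "focal")
  expect_equal(length(m1$C@x), length(py) * (length(py) - 1L))
  expect_true(all(m1$C[py, py][upper.tri(diag(length(py)))] == 0.1))
  expect_true(all(Matrix::diag(m1$C) == 0))
  # determinism
  m2 <- sample_matrix(lay, tau_steps = 11, seed = 7)
  m3 <- sample_matrix(lay, tau_steps = 11, seed = 7)
  expect_identical(as.matrix(m2$C), as.matrix(m3$C))
  # Dale sign rule: column sign fixed by source population
  pops <- swdnet:::node_populations(lay)
  T <- as(m2$C, "TsparseMatrix")
  src_sign <- swdnet:::POPULATION_SIGN[pops[T@j + 1L]]
  expect_true(all(sign(T@x) == src_sign))
  # structural soundness: no edges where the table prints "-"
  re <- layout_indices(lay, "RE", "focal")
  in_f <- layout_indices(lay, "IN", "focal")
  expect_equal(sum(abs(m2$C[py, re])), 0)   # PY never receives from RE
  expect_equal(sum(abs(m2$C[re, in_f])), 0) # RE never receives from IN
  nt <- layout_indices(lay, "NT")
  expect_equal(sum(abs(m2$C[nt, ])), 0)     # NT receives nothing
})

test_that("empirical edge density concentrates on the table probability", {
  # binomial oracle: over many seeds, the pooled PYf->PYf edge count behaves
  # as Binomial(n_pairs * n_seeds, 0.036); check within 3 binomial SEs
  lay <- tiny_layout(40, "PY", "focal")
  p <- coupling_probabilities()
  n_pairs <- 40 * 39
  n_seeds <- 50
  count <- 0
  for (seed in seq_len(n_seeds))
    count <- count + length(sample_matrix(lay, p, tau_steps = 9,
                                          seed = 1000 + seed)$C@x)
  n_tot <- n_pairs * n_seeds
  p_hat <- count / n_tot
  se <- sqrt(0.036 * (1 - 0.036) / n_tot)
  expect_lt(abs(p_hat - 0.036), 3 * se)
})

test_that("collateral completion follows the source-population sign rule", {
  counts <- c(PY.focal = 1L, TC.focal = 1L, RE.focal = 1L)
  lay <- network_layout("focal", counts = c(counts, NT.external = 0L,
                                            IN.focal = 0L))
  ipy <- layout_indices(lay, "PY"); itc <- layout_indices(lay, "TC")
  ire <- layout_indices(lay, "RE")
  # single edge PY -> TC (+0.1): collateral TC -> PY must be +0.1
  m <- manual_matrix(lay, i = itc, j = ipy, x = 0.1)
  mc <- apply_collaterals(m)
  expect_equal(mc$C[ipy, itc], 0.1)
  # single edge PY -> RE (+0.1): collateral RE -> PY must be -0.1
  m2 <- manual_matrix(lay, i = ire, j = ipy, x = 0.1)
  mc2 <- apply_collaterals(m2)
  expect_equal(mc2$C[ipy, ire], -0.1)
  # idempotence
  mc3 <- apply_collaterals(mc2)
  expect_identical(as.matrix(mc3$C), as.matrix(mc2$C))
  # mirror rule copies the forward value instead
  mm <- apply_collaterals(m2, rule = "mirror")
  expect_equal(mm$C[ipy, ire], 0.1)
  expect_identical(as.matrix(apply_collaterals(mm, rule = "mirror")$C),
                   as.matrix(mm$C))
})

test_that("collaterals never create edges into NT by default", {
  lay <- network_layout("focal")
  m <- apply_collaterals(sample_matrix(lay, tau_steps = 9, seed = 3))
  nt <- layout_indices(lay, "NT")
  expect_equal(sum(abs(m$C[nt, ])), 0)
})

test_that("composition places blocks correctly and enforces shared delay", {
  mf <- sample_matrix(network_layout("focal"), tau_steps = 10, seed = 1)
  ms <- sample_matrix(network_layout("surrounding"), tau_steps = 10, seed = 2)
  ms11 <- sample_matrix(network_layout("surrounding"), tau_steps = 11,
                        seed = 2)
  expect_error(compose_network(mf, ms11), "tau_steps")
  # zero cross probabilities -> block diagonal
  p0 <- coupling_probabilities()
  p0$surrounding <- 0
  mc0 <- compose_network(mf, ms, probs = p0, seed = 5, collaterals = FALSE)
  lay <- mc0$layout
  foc <- layout_indices(lay, region = c("focal", "external"))
  sur <- layout_indices(lay, region = "surrounding")
  expect_equal(sum(abs(mc0$C[foc, sur])), 0)
  expect_equal(sum(abs(mc0$C[sur, foc])), 0)
  # diagonal blocks preserve the input matrices
  expect_equal(sum(abs(mc0$C[foc, foc])), sum(abs(mf$C)))
  expect_equal(sum(abs(mc0$C[sur, sur])), sum(abs(ms$C)))
  # with the real table, cross blocks appear only where allowed, and the
  # PYf -> PYs bridge exists
  mc <- compose_network(mf, ms, seed = 5, collaterals = FALSE)
  pyf <- layout_indices(lay, "PY", "focal")
  pys <- layout_indices(lay, "PY", "surrounding")
  res <- layout_indices(lay, "RE", "surrounding")
  expect_gt(Matrix::nnzero(mc$C[pys, pyf]), 0)
  expect_equal(sum(abs(mc$C[pys, res])), 0)  # PY never receives from RE
  nt <- layout_indices(lay, "NT")
  tcs <- layout_indices(lay, "TC", "surrounding")
  expect_equal(sum(abs(mc$C[tcs, nt])), 0)   # NT drives focal TC only
})

test_that("matrix serialization round-trips losslessly", {
  m <- apply_collaterals(sample_matrix(network_layout("focal"),
                                       tau_steps = 12, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_coupling_matrix(m, path)
  m2 <- read_coupling_matrix(path)
  expect_identical(as.matrix(m$C), as.matrix(m2$C))
  expect_identical(m$tau_steps, m2$tau_steps)
  expect_identical(m$layout$n, m2$layout$n)
  expect_identical(m$layout$population, m2$layout$population)
  expect_equal(m$w_exc, m2$w_exc)
  # empty edge list with a valid header -> zero matrix of declared size
  m0 <- manual_matrix(network_layout("surrounding"))
  path0 <- tempfile(fileext = ".tsv")
  write_coupling_matrix(m0, path0)
  m0r <- read_coupling_matrix(path0)
  expect_equal(length(m0r$C@x), 0L)
  expect_equal(nrow(m0r$C), attr(network_layout("surrounding"), "n_total"))
  # a self-coupling triplet is rejected with the offending line named
  bad <- readLines(path)
  bad <- c(bad[startsWith(bad, "#")], "5\t5\t0.1")
  path_bad <- tempfile(fileext = ".tsv")
  writeLines(bad, path_bad)
  expect_error(read_coupling_matrix(path_bad), "self-coupling on line")
  # malformed triplet line is reported
  bad2 <- c(bad[startsWith(bad, "#")], "1\ttwo")
  path_bad2 <- tempfile(fileext = ".tsv")
  writeLines(bad2, path_bad2)
  expect_error(read_coupling_matrix(path_bad2), "line")
})
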