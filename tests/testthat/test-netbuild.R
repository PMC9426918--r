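test_that("window construction collapses repeated ties and sums MME", {
  rx <- data.frame(patient_id = c("P1", "P1"), provider_id = c("D1", "D1"),
                   quarter = c(1L, 2L), mme = c(30, 45))
  uw <- build_window_network(rx, end_quarter = 2, window_quarters = 3)
  expect_equal(as.numeric(uw$W["D1", "P1"]), 1)  # repeated ties not valued
  w <- build_window_network(rx, end_quarter = 2, window_quarters = 3,
                            weighted = TRUE)
  expect_equal(as.numeric(w$W["D1", "P1"]), 75)
})

test_that("the window boundary is inclusive on both ends", {
  rx <- data.frame(patient_id = "P1", provider_id = "D1",
                   quarter = 2L, mme = 10)
  # quarter end - 3 lies outside a 3-quarter window ending at end
  net <- build_window_network(rx, end_quarter = 5, window_quarters = 3)
  expect_equal(ncol(net$W), 0L)
  net <- build_window_network(rx, end_quarter = 4, window_quarters = 3)
  expect_equal(ncol(net$W), 1L)
})

test_that("empty windows return a valid empty network", {
  expect_message(
    net <- build_window_network(toy_records(), end_quarter = 9,
                                window_quarters = 1),
    "empty window")
  expect_equal(dim(net$W), c(0L, 0L))
})

test_that("patient projection counts distinct shared providers", {
  # path P1 - D1 - P2: one shared provider
  rx <- data.frame(patient_id = c("P1", "P2"), provider_id = c("D1", "D1"),
                   quarter = 0L, mme = 1)
  A <- project_patients(build_window_network(rx, 0, 1))$A
  expect_equal(as.numeric(A["P1", "P2"]), 1)

  # two shared providers
  rx2 <- data.frame(patient_id = c("P1", "P2", "P1", "P2"),
                    provider_id = c("D1", "D1", "D2", "D2"),
                    quarter = 0L, mme = 1)
  A2 <- project_patients(build_window_network(rx2, 0, 1))$A
  expect_equal(as.numeric(A2["P1", "P2"]), 2)
  expect_equal(as.numeric(Matrix::diag(A2)), c(0, 0))

  # a patient with a unique provider is isolated in the projection
  rx3 <- rbind(rx2, data.frame(patient_id = "P3", provider_id = "D9",
                               quarter = 0L, mme = 1))
  A3 <- project_patients(build_window_network(rx3, 0, 1))$A
  expect_equal(sum(A3["P3", ]), 0)
})

test_that("projection equals brute-force shared-provider counts", {
  sim <- small_sim()
  net <- build_window_network(sim$prescriptions, 4, 3)
  A <- project_patients(net)$A
  B <- as.matrix(net$W) > 0
  for (pair in list(c(1, 2), c(5, 40), c(10, 11), c(100, 200))) {
    u <- pair[1]; v <- pair[2]
    expect_equal(as.numeric(A[u, v]), sum(B[, u] & B[, v]))
  }
  # structural identity: A = t(B) B with a zeroed diagonal
  M <- crossprod(B * 1)
  diag(M) <- 0
  expect_equal(max(abs(as.matrix(A) - M)), 0)
})

test_that("degree and transitive-tie covariates match hand counts", {
  # star: one provider, five patients
  star <- data.frame(patient_id = paste0("P", 1:5), provider_id = "D1",
                     quarter = 0L, mme = 1)
  cov <- patient_covariates(build_window_network(star, 0, 1))
  expect_true(all(cov$degree == 1))
  expect_true(all(cov$transitive_ties == 4))

  # isolated dyad
  dyad <- data.frame(patient_id = "P1", provider_id = "D1",
                     quarter = 0L, mme = 1)
  cov2 <- patient_covariates(build_window_network(dyad, 0, 1))
  expect_equal(cov2$degree, 1)
  expect_equal(cov2$transitive_ties, 0)

  # two-provider patient: providers serve 3 and 4 other distinct patients
  # with exactly 1 overlap -> union of alters has 6 members
  rx <- data.frame(
    patient_id = c("PX", "PX", "A1", "A2", "A3", "B1", "B2", "B3", "A3"),
    provider_id = c("D1", "D2", "D1", "D1", "D1", "D2", "D2", "D2", "D2"),
    quarter = 0L, mme = 1)
  cov3 <- patient_covariates(build_window_network(rx, 0, 1))
  expect_equal(cov3$transitive_ties[cov3$patient_id == "PX"], 6)
})

test_that("degree assortativity matches the direct Pearson formula", {
  # complete bipartite K_{2,2}: all degrees equal, undefined
  k22 <- data.frame(patient_id = c("P1", "P2", "P1", "P2"),
                    provider_id = c("D1", "D1", "D2", "D2"),
                    quarter = 0L, mme = 1)
  expect_warning(r <- degree_assortativity(build_window_network(k22, 0, 1)),
                 "constant")
  expect_true(is.na(r))

  # high-degree patient attached only to degree-1 providers -> negative
  neg <- data.frame(
    patient_id = c("PH", "PH", "PH", "P1", "P2"),
    provider_id = c("D1", "D2", "D3", "D4", "D4"),
    quarter = 0L, mme = 1)
  expect_lt(degree_assortativity(build_window_network(neg, 0, 1)), 0)

  # arbitrary 6-edge toy graph equals Pearson over the edge list
  toy <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    provider_id = c("D1", "D2", "D1", "D1", "D3", "D3"),
    quarter = 0L, mme = 1)
  net <- build_window_network(toy, 0, 1)
  idx <- Matrix::which(net$W != 0, arr.ind = TRUE)
  ddeg <- Matrix::rowSums(net$W > 0)
  pdeg <- Matrix::colSums(net$W > 0)
  expect_equal(degree_assortativity(net),
               cor(pdeg[idx[, 2]], ddeg[idx[, 1]]))
})

test_that("components agree with an independent union-find oracle", {
  one <- build_window_network(toy_records(), 2, 3)
  comps <- network_components(one)
  oracle <- uf_components(toy_records()$provider_id,
                          toy_records()$patient_id)
  expect_equal(nrow(comps$sizes), oracle$n_components)
  expect_equal(comps$coverage, as.numeric(oracle$coverage))

  # two disjoint dyads
  dy <- data.frame(patient_id = c("P1", "P2"), provider_id = c("D1", "D2"),
                   quarter = 0L, mme = 1)
  sizes <- network_components(build_window_network(dy, 0, 1))$sizes
  expect_equal(nrow(sizes), 2L)
  expect_true(all(sizes$n_nodes == 2))

  # generated network vs oracle
  sim <- small_sim()
  net <- build_window_network(sim$prescriptions, 4, 3)
  idx <- Matrix::which(net$W != 0, arr.ind = TRUE)
  oracle <- uf_components(net$provider_ids[idx[, 1]],
                          net$patient_ids[idx[, 2]])
  got <- network_components(net)
  expect_equal(nrow(got$sizes), oracle$n_components)
  expect_equal(got$coverage, as.numeric(oracle$coverage))
})

test_that("window edge sets nest and weighting preserves sparsity", {
  sim <- small_sim()
  q <- 5
  n1 <- build_window_network(sim$prescriptions, q, 1)
  n3 <- build_window_network(sim$prescriptions, q, 3)
  e1 <- paste(n1$provider_ids[Matrix::which(n1$W != 0, arr.ind = TRUE)[, 1]],
              n1$patient_ids[Matrix::which(n1$W != 0, arr.ind = TRUE)[, 2]])
  e3 <- paste(n3$provider_ids[Matrix::which(n3$W != 0, arr.ind = TRUE)[, 1]],
              n3$patient_ids[Matrix::which(n3$W != 0, arr.ind = TRUE)[, 2]])
  expect_true(all(e1 %in% e3))

  w3 <- build_window_network(sim$prescriptions, q, 3, weighted = TRUE)
  expect_identical(dim(w3$W), dim(n3$W))
  expect_equal(as.matrix(w3$W != 0), as.matrix(n3$W != 0))
})

test_that("edge lists round trip and duplicate rows sum with a warning", {
  net <- build_window_network(toy_records(), 2, 3, weighted = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_equal(as.matrix(back$W), as.matrix(net$W))
  expect_equal(back$patient_ids, net$patient_ids)

  writeLines(c("provider_id\tpatient_id\tweight",
               "D1\tP1\t2", "D1\tP1\t3"), f)
  expect_warning(dup <- read_edge_list(f), "summed")
  expect_equal(as.numeric(dup$W["D1", "P1"]), 5)

  # empty network writes a header-only file that reads back empty
  empty <- build_window_network(toy_records()[0, ], 0, 1)
  write_edge_list(empty, f)
  expect_equal(dim(read_edge_list(f)$W), c(0L, 0L))
})

test_that("matrix-exchange export writes the matrix and its index sidecar", {
  net <- build_window_network(toy_records(), 2, 3, weighted = TRUE)
  f <- withr::local_tempfile(fileext = ".mtx")
  write_network_mtx(net, f)
  M <- Matrix::readMM(f)
  expect_equal(as.matrix(M), unname(as.matrix(net$W)))
  idx <- read.table(paste0(f, ".index.tsv"), header = TRUE, sep = "\t")
  expect_equal(sum(idx$mode == "row_provider"), nrow(net$W))
})
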