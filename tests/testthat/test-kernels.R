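test_that("marker QC applies missingness then MAF rules and mean-imputes", {
  # marker m1: MAF 0.04 (one 0 among 25 lines, rest 2) -> removed
  # marker m2: 71% missing -> removed; m3: 70% missing -> retained
  # marker m4: (0, 2, NA, ...) -> imputed 1.0
  n <- 100
  codes <- cbind(m1 = c(0, rep(2, 24), rep(2, n - 25)),
                 m2 = c(rep(NA, 71), rep(c(0, 2), length.out = n - 71)),
                 m3 = c(rep(NA, 70), rep(c(0, 2), length.out = n - 70)),
                 m4 = c(0, 2, NA, rep(c(0, 2), length.out = n - 3)))
  codes[1, "m1"] <- 0
  maf1 <- min(mean(codes[, "m1"]) / 2, 1 - mean(codes[, "m1"]) / 2)
  expect_lt(maf1, 0.05)
  m <- structure(list(line_ids = sprintf("L%03d", 1:n),
                      marker_ids = colnames(codes), codes = codes),
                 class = "MarkerMatrix")
  out <- suppressMessages(qcMarkers(m))
  rep <- out$report
  expect_equal(rep$n_input_markers, 4)
  expect_equal(rep$n_removed_missing, 1)
  expect_equal(rep$n_removed_maf, 1)
  expect_equal(rep$n_retained, 2)
  expect_equal(rep$n_input_markers,
               rep$n_removed_missing + rep$n_removed_maf + rep$n_retained)
  expect_setequal(out$markers$marker_ids, c("m3", "m4"))
  expect_equal(unname(out$markers$codes[3, "m4"]),
               mean(codes[-3, "m4"], na.rm = TRUE))
  expect_false(any(is.na(out$markers$codes)))
  # column (0, 2, missing) imputes to exactly the observed mean 1.0
  m2 <- structure(list(line_ids = c("a", "b", "c"), marker_ids = "x",
                       codes = matrix(c(0, 2, NA), 3, 1,
                                      dimnames = list(NULL, "x"))),
                  class = "MarkerMatrix")
  expect_equal(unname(suppressMessages(qcMarkers(m2))$markers$codes[3, 1]), 1.0)
})

test_that("VanRaden G matches hand and brute-force evaluations", {
  m <- structure(list(line_ids = c("a", "b"), marker_ids = "m1",
                      codes = matrix(c(0, 2), 2, 1,
                                     dimnames = list(c("a", "b"), "m1"))),
                 class = "MarkerMatrix")
  G <- genomicRelationship(m)
  expect_equal(unname(kernelValues(G)),
               matrix(c(2, -2, -2, 2), 2, 2), tolerance = 1e-12)

  # duplicate lines give identical rows/columns
  set.seed(3)
  codes <- matrix(sample(0:2, 5 * 30, replace = TRUE), 5, 30)
  codes[2, ] <- codes[1, ]
  rownames(codes) <- sprintf("L%d", 1:5)
  m2 <- structure(list(line_ids = rownames(codes),
                       marker_ids = sprintf("m%d", 1:30), codes = codes),
                  class = "MarkerMatrix")
  G2 <- kernelValues(genomicRelationship(m2))
  expect_equal(G2[1, ], G2[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # brute-force oracle on a random 20 x 50 matrix
  set.seed(11)
  codes <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
  rownames(codes) <- sprintf("L%02d", 1:20)
  m3 <- structure(list(line_ids = rownames(codes),
                       marker_ids = sprintf("m%d", 1:50), codes = codes),
                  class = "MarkerMatrix")
  p <- colMeans(codes) / 2
  Z <- codes - matrix(2 * p, 20, 50, byrow = TRUE)
  Gref <- (Z %*% t(Z)) / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(kernelValues(genomicRelationship(m3)) - Gref)), 1e-12)

  mono <- structure(list(line_ids = c("a", "b"), marker_ids = "m",
                         codes = matrix(c(2, 2), 2, 1)),
                    class = "MarkerMatrix")
  expect_error(genomicRelationship(mono), "monomorphic")
})

test_that("tabular pedigree relationships match hand-computed values", {
  ped <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(line_id = r[1], parent1 = r[2], parent2 = r[3],
                 stringsAsFactors = FALSE)))
  }
  # 1) unrelated non-inbred founders
  A1 <- kernelValues(pedigreeRelationship(
    ped(c("a", NA, NA), c("b", NA, NA), c("c", NA, NA))))
  expect_equal(unname(A1), diag(3))
  # 2) parent-offspring with one unknown parent: A = 0.5
  A2 <- kernelValues(pedigreeRelationship(
    ped(c("p", NA, NA), c("o", "p", NA))))
  expect_equal(A2["p", "o"], 0.5)
  expect_equal(unname(diag(A2)), c(1, 1))
  # 3) full sibs from two unrelated non-inbred founders
  A3 <- kernelValues(pedigreeRelationship(
    ped(c("s", NA, NA), c("d", NA, NA), c("k1", "s", "d"),
        c("k2", "s", "d"))))
  expect_equal(A3["k1", "k2"], 0.5)
  expect_equal(A3["k1", "k1"], 1.0)
  expect_equal(A3["s", "k1"], 0.5)
  # 4) fully inbred founders: diagonal 2, full sibs 1, sib diagonal 1.5
  A4 <- kernelValues(pedigreeRelationship(
    ped(c("s", NA, NA), c("d", NA, NA), c("k1", "s", "d"),
        c("k2", "s", "d")), inbredFounders = TRUE))
  expect_equal(A4["s", "s"], 2.0)
  expect_equal(A4["k1", "k2"], 1.0)      # 0.5*(A[k2,s]+A[k2,d]) = 0.5*(1+1)
  expect_equal(A4["k1", "k1"], 1.0)      # parents unrelated: 1 + 0.5*0
  # 5) grandparent and half sibs
  A5 <- kernelValues(pedigreeRelationship(
    ped(c("g", NA, NA), c("m1", NA, NA), c("m2", NA, NA),
        c("c1", "g", "m1"), c("c2", "g", "m2"),
        c("gc", "c1", NA))))
  expect_equal(A5["g", "gc"], 0.25)      # grandparent
  expect_equal(A5["c1", "c2"], 0.25)     # half sibs
  # 6) offspring of full sibs is inbred: F = 0.25
  A6 <- kernelValues(pedigreeRelationship(
    ped(c("s", NA, NA), c("d", NA, NA), c("k1", "s", "d"),
        c("k2", "s", "d"), c("x", "k1", "k2"))))
  expect_equal(A6["x", "x"], 1.25)
  # unknown line referenced as parent
  expect_error(pedigreeRelationship(ped(c("o", "ghost", NA))),
               "unknown line")
})

test_that("spectral H has the documented centering, scaling and trace", {
  # 2 lines, 1 band, raw (3, 5): centered (-1, 1), sample sd sqrt(2)
  H1 <- kernelValues(spectralRelationship(
    matrix(c(3, 5), 2, 1, dimnames = list(c("a", "b"), "b500"))))
  expect_equal(unname(H1), matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)
  # identical rows annihilate under centering
  H0 <- kernelValues(suppressWarnings(spectralRelationship(
    matrix(1.7, 4, 5, dimnames = list(letters[1:4], NULL)))))
  expect_equal(unname(H0), matrix(0, 4, 4))
  # random 15 x 62: trace n-1, zero row sums, PSD
  set.seed(5)
  B <- matrix(rnorm(15 * 62), 15, dimnames = list(sprintf("L%02d", 1:15), NULL))
  H <- spectralRelationship(B)
  expect_equal(sum(diag(kernelValues(H))), 14, tolerance = 1e-9)
  expect_lt(max(abs(rowSums(kernelValues(H)))), 1e-9)
  expect_true(isPSD(H))
  # constant band dropped with adjusted divisor
  B2 <- cbind(B[, 1:3], const = 1)
  expect_warning(H2 <- spectralRelationship(B2), "constant band")
  expect_equal(sum(diag(kernelValues(H2))), 14, tolerance = 1e-9)
  expect_error(spectralRelationship(B[1, , drop = FALSE]), "at least 2")
})

test_that("kernel expansion matches the dense Hadamard oracle and block structure", {
  set.seed(21)
  lines <- sprintf("g%d", 1:5)
  M <- crossprod(matrix(rnorm(25), 5)) / 5
  dimnames(M) <- list(lines, lines)
  K <- RelationshipMatrix(M, kind = "G")
  ph <- data.frame(
    site_year = rep(c("2013-14:Heat", "2014-15:Heat"), each = 4),
    line_id = c(lines[1:4], lines[2:5]), stringsAsFactors = FALSE)
  idx <- buildRecordIndex(ph)
  expect_equal(nRecords(idx), 8)
  main <- expandKernel(K, idx, "main")
  gxe <- expandKernel(K, idx, "gxe")
  # dense brute-force oracle
  recs <- recordTable(idx)
  Zg <- outer(recs$line_id, lines, "==") * 1
  sameEnv <- outer(recs$site_year, recs$site_year, "==") * 1
  expect_lt(max(abs(main - Zg %*% M %*% t(Zg))), 1e-12)
  expect_lt(max(abs(gxe - (Zg %*% M %*% t(Zg)) * sameEnv)), 1e-12)
  off <- outer(recs$site_year, recs$site_year, "!=")
  expect_true(all(gxe[off] == 0))
  # restriction property: one site-year's gxe block equals the main block
  sel <- recs$site_year == "2013-14:Heat"
  expect_equal(gxe[sel, sel], main[sel, sel])
  # single site-year: gxe equals main entrywise
  idx1 <- buildRecordIndex(ph[ph$site_year == "2013-14:Heat", ])
  expect_equal(expandKernel(K, idx1, "gxe"), expandKernel(K, idx1, "main"))
  # block_h assembly aligns per-site-year H blocks
  hA <- RelationshipMatrix(M[1:4, 1:4], kind = "H")
  hB <- RelationshipMatrix(M[2:5, 2:5], kind = "H")
  bh <- expandKernel(list("2013-14:Heat" = hA, "2014-15:Heat" = hB),
                     idx, "block_h")
  expect_true(all(bh[off] == 0))
  expect_equal(unname(bh[sel, sel]), unname(M[recs$line_id[sel],
                                              recs$line_id[sel]]))
  expect_error(expandKernel(list("2013-14:Heat" = hA), idx, "block_h"),
               "coverage")
  # genotype missing from the kernel
  idxBad <- buildRecordIndex(data.frame(site_year = "2013-14:Heat",
                                        line_id = c(lines[1:2], "novel")))
  expect_error(expandKernel(K, idxBad, "main"), "coverage")
})

test_that("relationship matrices round-trip through CSV", {
  set.seed(6)
  M <- crossprod(matrix(rnorm(16), 4)) / 4
  dimnames(M) <- list(sprintf("L%d", 1:4), sprintf("L%d", 1:4))
  k <- RelationshipMatrix(M, kind = "A")
  p <- tempfile(fileext = ".csv")
  writeRelationshipMatrix(k, p)
  k2 <- readRelationshipMatrix(p, kind = "A")
  expect_equal(kernelIds(k2), kernelIds(k))
  expect_equal(kernelValues(k2), kernelValues(k), tolerance = 1e-12)
})

test_that("G on simulated full-sib families reflects family structure", {
  cfg <- simConfig(nFamilies = 40, sibsPerFamily = 2, nFounders = 30,
                   nMarkers = 600, cycles = "2013-14",
                   treatments = "Optimal Bed", masterSeed = 9)
  pop <- simulatePopulation(cfg)
  G <- kernelValues(suppressMessages(
    genomicRelationship(suppressMessages(qcMarkers(pop$markers))$markers)))
  fams <- sub("_[12]$", "", rownames(G))
  sameFam <- outer(fams, fams, "==") & upper.tri(G)
  diffFam <- outer(fams, fams, "!=") & upper.tri(G)
  expect_gt(mean(G[sameFam]), mean(G[diffFam]))
  # full-sib relatedness around half the diagonal mean
  expect_lt(abs(mean(G[sameFam]) - 0.5 * mean(diag(G))), 0.1 * mean(diag(G)))
})
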