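test_that("erosion keeps only pixels where the element fits", {
  B <- matrix(FALSE, 5, 5); B[2:4, 2:4] <- TRUE
  E <- erode_mask(B)
  expect_equal(sum(E), 1L)
  expect_true(E[3, 3])

  expect_equal(sum(erode_mask(matrix(FALSE, 5, 5))), 0L)

  # all-true mask erodes its one-pixel border
  E <- erode_mask(matrix(TRUE, 5, 5))
  expect_true(all(E[2:4, 2:4]))
  expect_equal(sum(E), 9L)
  expect_error(erode_mask(B, matrix(FALSE, 3, 3)), "TRUE")
})

test_that("dilation spreads single pixels and satisfies interior duality", {
  B <- matrix(FALSE, 5, 5); B[3, 3] <- TRUE
  D <- dilate_mask(B)
  expect_true(all(D[2:4, 2:4]))
  expect_equal(sum(D), 9L)
  expect_equal(sum(dilate_mask(matrix(FALSE, 4, 4))), 0L)

  # duality against erosion of the complement with the reflected element,
  # away from the border (the border convention pads background for both
  # operators, which breaks duality only in the outermost ring)
  S <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
              3, 3)
  Sr <- S[3:1, 3:1]
  set.seed(6)
  for (i in 1:25) {
    B <- random_mask(9, p = 0.4)
    lhs <- dilate_mask(B, S)
    rhs <- !erode_mask(!B, Sr)
    expect_identical(lhs[2:8, 2:8], rhs[2:8, 2:8])
  }
})

test_that("opening removes specks, preserves blocks, and is idempotent", {
  B <- matrix(FALSE, 7, 7); B[4, 4] <- TRUE
  expect_equal(sum(open_mask(B)), 0L)

  block <- matrix(FALSE, 14, 14); block[3:12, 3:12] <- TRUE
  expect_identical(open_mask(block), block)

  set.seed(7)
  for (i in 1:100) {
    B <- random_mask(8, p = stats::runif(1, 0.2, 0.8))
    O <- open_mask(B)
    expect_identical(open_mask(O), O)   # idempotent
    expect_true(all(O <= B))            # anti-extensive
  }
})

test_that("erosion is anti-extensive and monotone", {
  set.seed(8)
  for (i in 1:50) {
    B1 <- random_mask(8, p = 0.5)
    B2 <- B1 | random_mask(8, p = 0.2)
    E1 <- erode_mask(B1); E2 <- erode_mask(B2)
    expect_true(all(E1 <= B1))
    expect_true(all(E1 <= E2))
  }
})

test_that("morphology matches set-definition brute force on all 3x3 masks", {
  # the full 4x4 enumeration runs in the acceptance suite
  nr <- 3L; nc <- 3L
  n_masks <- 2L^(nr * nc)
  bits <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nr * nc)))
  M <- t(bits)   # 16 x 65536, column k = mask k (column-major pixels)
  S <- structuring_element("square", 3L)
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))

  oE <- oracle_erode_cols(M, nr, nc, off)
  oD <- oracle_dilate_cols(M, nr, nc, off)
  oO <- oracle_dilate_cols(oE, nr, nc, off)

  iE <- matrix(FALSE, nr * nc, n_masks)
  iD <- matrix(FALSE, nr * nc, n_masks)
  iO <- matrix(FALSE, nr * nc, n_masks)
  for (k in seq_len(n_masks)) {
    B <- matrix(M[, k], nr, nc)
    e <- erode_mask(B, S)
    iE[, k] <- e
    iD[, k] <- dilate_mask(B, S)
    iO[, k] <- dilate_mask(e, S)
  }
  expect_identical(iE, oE)
  expect_identical(iD, oD)
  expect_identical(iO, oO)
})

test_that("refinement erodes then opens and never adds foreground", {
  B <- matrix(FALSE, 20, 20)
  B[5:16, 5:16] <- TRUE                      # solid block
  B[2, 2] <- TRUE; B[18, 3] <- TRUE          # 1-px specks
  B[2, 18] <- TRUE; B[3, 18] <- TRUE         # 2-px speck
  R <- refine_mask(B)
  expect_equal(sum(R[1:3, ]), 0L)            # specks gone
  expect_true(all(R[7:14, 7:14]))            # block interior retained
  expect_true(all(R <= B))

  expect_equal(sum(refine_mask(matrix(FALSE, 6, 6))), 0L)
  expect_identical(refine_mask(B), open_mask(erode_mask(B)))

  set.seed(9)
  for (i in 1:20) {
    B <- random_mask(10, p = 0.6)
    expect_true(all(refine_mask(B) <= B))
  }
})

test_that("structuring elements validate and disks are symmetric", {
  expect_error(structuring_element(size = 4L), "odd")
  D <- structuring_element("disk", 5L)
  expect_true(D[3, 3])
  expect_identical(unclass(D), unclass(D)[5:1, 5:1])
  expect_false(D[1, 1])
})

test_that("mask application zeroes exactly the background", {
  img <- random_image(10, seed = 10)
  expect_identical(as.integer(apply_mask(img, matrix(TRUE, 10, 10))),
                   as.integer(img))
  expect_true(all(apply_mask(img, matrix(FALSE, 10, 10)) == 0L))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  out <- apply_mask(img, half)
  expect_identical(as.integer(out[, 1:5]), as.integer(img[, 1:5]))
  expect_true(all(out[, 6:10] == 0L))
  expect_error(apply_mask(img, matrix(TRUE, 5, 5)), "shape")
})
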