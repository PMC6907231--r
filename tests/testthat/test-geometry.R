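test_that("boundingBox encloses points and rectangles minimally", {
  expect_equal(unname(boundingBox(list(c(3, 4)))), c(3, 4, 3, 4))
  expect_equal(unname(boundingBox(list(c(0, 0), c(2, 5)))), c(0, 0, 2, 5))
  expect_equal(unname(boundingBox(list(c(0, 0, 1, 1), c(2, 2, 3, 3)))),
               c(0, 0, 3, 3))
  expect_error(boundingBox(list()), "no objects")
})

test_that("projectOnArrow gives normalized axis position and signed distance", {
  a <- list(tailx = 0, taily = 0, headx = 10, heady = 0)
  expect_equal(unname(projectOnArrow(c(0, 0), a)), c(0, 0))
  expect_equal(unname(projectOnArrow(c(10, 0), a)), c(1, 0))
  # above the arrow (smaller y) is negative
  expect_equal(unname(projectOnArrow(c(5, -3), a)), c(0.5, -3))
  expect_error(projectOnArrow(c(1, 1), list(tailx = 2, taily = 2,
                                            headx = 2, heady = 2)),
               "zero-length")
})

test_that("projection is invariant under simultaneous translation", {
  set.seed(42)
  for (i in 1:25) {
    p <- runif(2, -50, 50)
    a <- list(tailx = runif(1, -50, 50), taily = runif(1, -50, 50),
              headx = runif(1, -50, 50), heady = runif(1, -50, 50))
    if (a$tailx == a$headx && a$taily == a$heady) next
    d <- runif(2, -1000, 1000)
    a2 <- list(tailx = a$tailx + d[1], taily = a$taily + d[2],
               headx = a$headx + d[1], heady = a$heady + d[2])
    expect_equal(projectOnArrow(p + d, a2), projectOnArrow(p, a),
                 tolerance = 1e-9)
  }
})
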