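test_that("buildChain constructs labelled chains with uniform edge couplings", {
  net <- buildChain(61, 0.6)
  expect_s4_class(net, "CellNetwork")
  expect_equal(nrow(cells(net)), 61L)
  expect_equal(nrow(couplings(net)), 60L)
  expect_true(all(couplings(net)$kind == "edge"))
  expect_true(all(couplings(net)$coefficient == 0.6))
  expect_equal(cells(net)$label, as.character(1:61))
  expect_length(validateNetwork(net), 0L)

  tiny <- buildChain(2, 0.6)
  expect_equal(nrow(cells(tiny)), 2L)
  expect_equal(nrow(couplings(tiny)), 1L)

  zero <- buildChain(5, 0)
  expect_equal(nrow(couplings(zero)), 4L)
  expect_true(all(couplings(zero)$coefficient == 0))
})

test_that("buildChain rejects degenerate inputs", {
  expect_error(buildChain(1, 0.6), "n_cells")
  expect_error(buildChain(5, -0.1), "non-negative")
})

test_that("the T structure has the reconstructed topology", {
  net <- buildTStructure(0.6, 0.2, vertex_pairs = "all")
  cl <- cells(net)
  cp <- couplings(net)
  expect_equal(nrow(cl), 93L)   # 61 backbone + 30 branch + 2 cluster
  expect_length(validateNetwork(net), 0L)

  pair <- function(a, b) {
    any((cp$a == a & cp$b == b) | (cp$a == b & cp$b == a))
  }
  # the branch entrance is vertex-coupled to both flanking junction cells
  vkeys <- cp[cp$kind == "vertex", ]
  expect_true(pair("1s", "30"))
  expect_true(pair("1s", "32"))
  expect_equal(nrow(vkeys), 8L)
  expect_true(all(vkeys$coefficient == 0.2))

  # junction subset rule keeps the four entrance pairs only
  net4 <- buildTStructure(0.6, 0.2)
  v4 <- couplings(net4)[couplings(net4)$kind == "vertex", ]
  got <- sort(paste(pmin(v4$a, v4$b), pmax(v4$a, v4$b)))
  expect_equal(got, sort(c("1s 30", "1s 32", "1' 31", "2' 31")))

  # cluster cells attach by edges to their backbone cells and the branch
  expect_true(pair("30", "1'"))
  expect_true(pair("32", "2'"))
  expect_true(pair("1'", "1s"))
  expect_true(pair("2'", "1s"))
  expect_true(pair("31", "1s"))
})

test_that("T-structure degree and reflection-symmetry properties hold", {
  net <- buildTStructure(0.6, 0.2, vertex_pairs = "all")
  cp <- couplings(net)
  deg <- table(factor(c(cp$a, cp$b), levels = cells(net)$label))
  # backbone cells far from the junction are plain chain cells
  far <- setdiff(as.character(1:61), as.character(29:33))
  far <- setdiff(far, c("1", "61"))
  expect_true(all(deg[far] == 2L))
  # branch cells beyond row 2 are plain chain cells
  deep <- paste0(3:29, "s")
  expect_true(all(deg[deep] == 2L))

  # reflection about the column of cell 31
  mirror <- function(lbl) {
    cl <- cells(net)
    i <- match(lbl, cl$label)
    mcol <- 2L * 31L - cl$col[i]
    j <- which(cl$col == mcol & cl$row == cl$row[i])
    cl$label[j]
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  orig <- sort(key(cp$a, cp$b))
  refl <- sort(key(vapply(cp$a, mirror, ""), vapply(cp$b, mirror, "")))
  expect_equal(refl, orig)
})

test_that("validateNetwork reports violations without raising", {
  bad_pos <- cellNetwork(
    data.frame(label = c("a", "b"), col = c(1, 1), row = c(0, 0)),
    data.frame(a = "a", b = "b", kind = "edge", coefficient = 1)
  )
  v <- validateNetwork(bad_pos)
  expect_true(any(grepl("a, b", v) & grepl("share position", v)))

  # a coupling flagged edge between diagonal positions
  bad_kind <- cellNetwork(
    data.frame(label = c("a", "b"), col = c(1, 2), row = c(0, 1)),
    data.frame(a = "a", b = "b", kind = "edge", coefficient = 1)
  )
  v <- validateNetwork(bad_kind)
  expect_true(any(grepl("geometry implies 'vertex'", v)))

  disconnected <- cellNetwork(
    data.frame(label = c("a", "b", "c"), col = 1:3, row = 0),
    data.frame(a = "a", b = "b", kind = "edge", coefficient = 1)
  )
  expect_true(any(grepl("not connected", validateNetwork(disconnected))))
})

test_that("network JSON round-trips exactly", {
  net <- buildTStructure(0.6, 0.17)
  path <- tempfile(fileext = ".json")
  writeNetworkJSON(net, path)
  back <- readNetworkJSON(path)
  expect_identical(cells(back)$label, cells(net)$label)
  expect_identical(cells(back)$col, cells(net)$col)
  expect_identical(couplings(back)$kind, couplings(net)$kind)
  expect_identical(couplings(back)$coefficient, couplings(net)$coefficient)
  expect_identical(architecture(back), architecture(net))
  unlink(path)
})
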