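test_that("schema construction enforces its invariants", {
  expect_error(cat_schema(list(list(name = "", domain = "a"))), "non-empty")
  expect_error(cat_schema(list(list(name = "A", domain = character(0)))),
               "empty domain")
  expect_error(cat_schema(list(list(name = "A", domain = c("a", "a")))),
               "duplicate")
  expect_error(cat_schema(list(list(name = "A", domain = "a"),
                               list(name = "A", domain = "b"))), "unique")
  expect_error(cat_schema(list(list(name = "A", domain = "a", role = "class"),
                               list(name = "B", domain = "b", role = "class"))),
               "at most one")
})

test_that("a table rejects values outside the declared domain and missing labels", {
  schema <- cat_schema(list(list(name = "A", domain = c("a", "b")),
                            list(name = "y", domain = c("p", "q"),
                                 role = "class")))
  expect_error(discrete_table(data.frame(A = "z", y = "p"), schema),
               "outside the domain")
  expect_error(discrete_table(data.frame(A = "a", y = NA), schema),
               "class column")
})

test_that("CSV round trip is the identity on cells and mask", {
  tab <- random_table(50, 6, miss_frac = 0.2, seed = 11)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_table(tab, p1)
  back <- read_table(p1, schema = tab$schema)
  expect_identical(back$data, tab$data)
  expect_identical(missing_mask(back), missing_mask(tab))
  # sentinel cells written as "?"
  raw <- readLines(p1)
  expect_true(any(grepl('"?"', raw, fixed = TRUE)))
  # byte-stable across two writes
  write_table(tab, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("schema inference sorts domains and assigns the class role to the last column", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("lymphatics,outcome",
               "normal,y", "arched,y", "deformed,n", "displaced,n", "?,y"), p)
  tab <- read_table(p)
  expect_identical(tab$schema$attributes[[1]]$domain,
                   c("arched", "deformed", "displaced", "normal"))
  expect_identical(tab$schema$attributes[[2]]$role, "class")
  expect_true(is.na(tab$data$lymphatics[5]))
  expect_equal(sum(missing_mask(tab)), 1L)
})

test_that("split_by_completeness partitions rows and reconstruct inverts it", {
  tab <- random_table(10, 4, seed = 3)
  for (r in c(2, 5, 9)) tab$data$A1[r] <- NA
  parts <- split_by_completeness(tab)
  expect_equal(n_rows <- nrow(parts$dcom$data), 7)
  expect_equal(nrow(parts$dmiss$data), 3)
  expect_length(intersect(parts$dcom$row_ids, parts$dmiss$row_ids), 0)
  back <- reconstruct(parts$dcom, parts$dmiss)
  expect_identical(back$data, tab$data)
  expect_identical(back$row_ids, tab$row_ids)
  # shuffled parts still come back in original order
  shuf <- parts$dmiss
  ord <- c(3, 1, 2)
  shuf <- discrete_table(shuf$data[ord, ], shuf$schema, shuf$row_ids[ord])
  expect_identical(reconstruct(parts$dcom, shuf)$data, tab$data)
  expect_error(reconstruct(parts$dcom, parts$dcom), "overlapping")
})

test_that("row-count conservation holds across random splits", {
  for (s in 1:20) {
    tab <- random_table(sample(5:40, 1), 3, miss_frac = 0.25, seed = s)
    parts <- split_by_completeness(tab)
    expect_equal(nrow(parts$dcom$data) + nrow(parts$dmiss$data),
                 nrow(tab$data))
    if (nrow(parts$dmiss$data) > 0) {
      expect_identical(reconstruct(parts$dcom, parts$dmiss)$data, tab$data)
    }
  }
})

test_that("detect_missing_types groups rows by their exact missing pattern", {
  tab <- random_table(6, 5, seed = 4)
  # masks {A1,A2,A5}, {A2}, {A3,A5}, {A2}, complete, {A1,A2,A5}
  tab$data$A1[c(1, 6)] <- NA; tab$data$A2[c(1, 2, 4, 6)] <- NA
  tab$data$A5[c(1, 3, 6)] <- NA; tab$data$A3[3] <- NA
  types <- detect_missing_types(tab)
  expect_length(types, 3)
  sets <- lapply(types, `[[`, "missing_attrs")
  expect_identical(sets, list(c(1L, 2L, 5L), 2L, c(3L, 5L)))
  expect_identical(types[[1]]$rows, c(1L, 6L))
  expect_identical(types[[2]]$rows, c(2L, 4L))
  # rows partition Dmiss exactly
  all_rows <- sort(unlist(lapply(types, `[[`, "rows")))
  expect_identical(all_rows, which(rowSums(missing_mask(tab)) > 0))
  # complete table has no types
  expect_length(detect_missing_types(random_table(5, 3, seed = 1)), 0)
})

test_that("detect_missing_types matches a brute-force grouping on random tables", {
  for (s in 1:10) {
    tab <- random_table(30, 4, miss_frac = 0.3, seed = 100 + s)
    m <- missing_mask(tab)
    keys <- apply(m[, 1:4, drop = FALSE] * 1L, 1, paste, collapse = "")
    expected <- sort(unique(keys[rowSums(m) > 0]))
    types <- detect_missing_types(tab)
    got <- sort(vapply(types, function(t) {
      paste(as.integer(seq_len(4) %in% t$missing_attrs), collapse = "")
    }, ""))
    expect_identical(got, expected)
    rows <- unlist(lapply(types, `[[`, "rows"))
    expect_false(any(duplicated(rows)))
    expect_setequal(rows, which(rowSums(m) > 0))
  }
})

test_that("one-hot layout and encoding follow domain order with one 1 per block", {
  schema <- cat_schema(list(
    list(name = "lymphatics",
         domain = c("normal", "arched", "deformed", "displaced")),
    list(name = "B", domain = c("x", "y")),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  tab <- discrete_table(
    data.frame(lymphatics = c("normal", "displaced"), B = c("y", "x"),
               cls = c("p", "q")), schema)
  layout <- onehot_layout(schema)
  expect_equal(layout$total_width, 4 + 2 + 2)
  X <- encode_one_hot(tab, layout)
  expect_equal(X[1, 1:4], c(1, 0, 0, 0))
  expect_equal(X[2, 1:4], c(0, 0, 0, 1))
  expect_true(all(rowSums(X) == 3))  # one 1 per attribute block
})

test_that("decoding takes the block argmax and ties break to the lowest domain index", {
  schema <- cat_schema(list(list(name = "A",
                                 domain = c("a", "b", "c", "d"))))
  layout <- onehot_layout(schema)
  expect_equal(
    unname(decode_one_hot(matrix(c(0.1, 0.9, 0.3, 0.2), 1), layout, 1)[1, 1]),
    "b")
  expect_equal(unname(decode_one_hot(matrix(0.5, 1, 4), layout, 1)[1, 1]), "a")
  expect_error(decode_one_hot(matrix(0, 1, 3), layout, 1), "width")
})

test_that("decode(encode(t)) is the identity on complete tables", {
  for (s in 1:25) {
    tab <- random_table(sample(2:40, 1), sample(2:6, 1), seed = 200 + s)
    layout <- onehot_layout(tab$schema)
    X <- encode_one_hot(tab, layout)
    dec <- decode_one_hot(X, layout)
    expect_identical(unname(dec), unname(as.matrix(tab$data)))
  }
})

test_that("encoding a missing cell is a precondition error naming the cell", {
  tab <- random_table(5, 3, seed = 2)
  tab$data$A2[3] <- NA
  layout <- onehot_layout(tab$schema)
  expect_error(encode_one_hot(tab, layout), "row 3, attribute 2")
})

test_that("numeric attributes scale to [0,1] from complete-row bounds and clip", {
  schema <- cat_schema(list(
    list(name = "A", domain = c("a", "b")),
    list(name = "num", kind = "numeric"),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  tab <- discrete_table(
    data.frame(A = c("a", "b", NA, "a"), num = c(0, 10, 20, 5),
               cls = c("p", "q", "p", "q")), schema)
  layout <- onehot_layout(schema, tab)
  # bounds from complete rows only: rows 1,2,4 -> [0,10]; row 3's 20 clips
  X <- encode_one_hot(tab, layout, rows = c(1, 2, 4))
  expect_equal(X[, 3], c(0, 1, 0.5))
  filled <- impute_mode(tab)
  expect_equal(encode_one_hot(filled, layout, rows = 3)[1, 3], 1)
})

test_that("schema JSON round trips", {
  tab <- random_table(5, 3, seed = 9)
  p <- tempfile(fileext = ".json")
  write_schema(tab$schema, p, missing_sentinel = "?")
  back <- read_schema(p)
  expect_identical(back$schema, tab$schema)
  expect_identical(back$missing_sentinel, "?")
})
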