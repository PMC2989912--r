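# shared fixture builders; everything is generated in code at test time

fix_window <- function(wx = 2000, wy = 1000) rectangle_window(0, wx, 0, wy)

# a small trap table with known hand-computable metrics
fix_trap_records <- function() {
  tibble::tibble(
    tree_id = c("a", "a", "a", "b", "b", "c"),
    season_id = c("s1", "s1", "s1", "s1", "s1", "s2"),
    day = c(200, 210, 220, 200, 220, 150),
    count = c(1L, 1L, 1L, 2L, 2L, 1L)
  )
}

# write a tree table CSV and return its path
fix_tree_csv <- function(dir, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(id = c("t1", "t2", "t3"),
                     x = c(100, 500, 900), y = c(100, 500, 900),
                     dbh = c(250, 600, 1200), visible = c(0, 0, 1))
  }
  path <- file.path(dir, "trees.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
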