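test_that("NEXUS parsing handles unknown, inapplicable and polymorphic cells", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=2;",
               "  FORMAT SYMBOLS=\"0 1\" MISSING=? GAP=-;",
               "  MATRIX", "    ta 01", "    tb 0?", "  ;", "END;"), f)
  m <- read_nexus(f)
  expect_equal(dim(m), c(2L, 2L))
  s <- summarize_matrix(m)
  expect_equal(s$pct_unknown, 25)
  expect_equal(s$pct_missing, 25)

  f2 <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=2;",
               "  FORMAT SYMBOLS=\"0 1\" MISSING=? GAP=-;",
               "  MATRIX", "    ta {01}1", "    tb 0-", "  ;", "END;"), f2)
  m2 <- read_nexus(f2)
  expect_equal(m2$kind[1, 1], "p")
  expect_equal(mc$mask_to_states(m2$masks[1, 1]), c(0L, 1L))
  expect_equal(m2$kind[2, 2], "i")
})

test_that("the bundled demo matrix reads with the declared dimensions", {
  m <- read_nexus(demo_path("demo_seeds.nex"))
  expect_equal(dim(m), c(8L, 12L))
  expect_equal(sum(m$kind == "p"), 1L)
  expect_equal(sum(m$kind == "i"), 1L)
  expect_equal(sum(m$kind == "u"), 2L)
})

test_that("write -> read is the identity on the grid, taxon order and symbols", {
  set.seed(11)
  for (rep in 1:5) {
    tok <- rand_tokens(7, 10, k = 3, p_unknown = 0.15, p_inapp = 0.1,
                       p_poly = 0.05)
    m <- morph_matrix(tok, symbols = as.character(0:2))
    f <- tempfile(fileext = ".nex")
    write_nexus(m, f)
    m2 <- read_nexus(f)
    expect_identical(m2$taxa, m$taxa)
    expect_identical(m2$masks, m$masks)
    expect_identical(m2$kind, m$kind)
    expect_identical(m2$symbols, m$symbols)
  }
})

test_that("structural errors are reported with the offending row or symbol", {
  bad_dim <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=3;",
               "  FORMAT SYMBOLS=\"0 1\";",
               "  MATRIX", "    ta 01", "    tb 00", "  ;", "END;"), bad_dim)
  expect_error(read_nexus(bad_dim), "ta")

  bad_sym <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=2;",
               "  FORMAT SYMBOLS=\"0 1\";",
               "  MATRIX", "    ta 01", "    tb 0X", "  ;", "END;"), bad_sym)
  expect_error(read_nexus(bad_sym), "X")

  dup <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=2;",
               "  FORMAT SYMBOLS=\"0 1\";",
               "  MATRIX", "    ta 01", "    ta 00", "  ;", "END;"), dup)
  expect_error(read_nexus(dup), "duplicate")
})

test_that("summary percentages are exact, additive and stored at full precision", {
  tok <- rand_tokens(9, 13, k = 2)          # 117 cells
  tok[1, 1] <- "?"; tok[2, 1] <- "?"; tok[3, 2] <- "-"
  m <- morph_matrix(tok)
  s <- summarize_matrix(m)
  expect_equal(s$n_cells, 117L)
  expect_equal(s$pct_unknown, 100 * 2 / 117)
  expect_equal(s$pct_inapplicable, 100 * 1 / 117)
  expect_equal(s$pct_missing, s$pct_unknown + s$pct_inapplicable)
  expect_equal(unname(s$per_taxon_pct_missing["t1"]), 100 * 1 / 13)
  expect_equal(which.max(s$per_character_pct_missing), c(C1 = 1L))

  full <- morph_matrix(rand_tokens(5, 5, k = 3))
  sf <- summarize_matrix(full)
  expect_equal(sf$pct_missing, 0)
  expect_equal(sf$pct_polymorphic, 0)
})

test_that("recoding turns polymorphic cells into unknown, leaving the rest", {
  tok <- rand_tokens(10, 10, k = 2)
  tok[c(3, 47, 92)] <- "{01}"
  m <- morph_matrix(tok)
  r <- recode_for_distance(m)
  expect_equal(sum(r$kind == "p"), 0L)
  before <- summarize_matrix(m)
  after <- summarize_matrix(r)
  expect_equal(after$pct_unknown,
               before$pct_unknown + before$pct_polymorphic)
  det <- m$kind == "d"
  expect_identical(r$masks[det], m$masks[det])
})

test_that("sidecar readers validate their inputs", {
  g <- tempfile()
  writeLines(c("ta\tg1", "tb\tg1", "ta\tg2"), g)
  expect_error(read_groups(g), "more than one group")
  g2 <- tempfile()
  writeLines(c("ta\tg1", "tb\tg2"), g2)
  expect_equal(read_groups(g2), list(g1 = "ta", g2 = "tb"))

  r <- tempfile()
  writeLines(c("ta\t350\t360"), r)          # fad < lad
  expect_error(read_strat_ranges(r), "ta")

  ct <- tempfile()
  writeLines(c("1\tarchitectural", "2\tcellular"), ct)
  expect_equal(read_categories(ct, 2), c("architectural", "cellular"))
  expect_error(read_categories(ct, 3), "cover")

  grp <- read_groups(demo_path("demo_groups.tsv"))
  expect_named(grp, c("cardiocarps", "lagenocarps", "trigonocarps"))
  rng <- read_strat_ranges(demo_path("demo_ranges.tsv"))
  expect_true(all(rng$fad >= rng$lad))
})
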