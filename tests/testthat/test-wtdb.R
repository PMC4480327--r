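# Core database layer: I/O, validation, aggregation, D5%.

make_table <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("species,field_code,value,units,source_quality", rows), path)
  path
}

test_that("read_trait_table parses, validates and round-trips", {
  path <- make_table(c(
    "Galium aparine,SEEDWEIGHT,6.64,mg,peer_reviewed",
    "Galium aparine,SEEDWEIGHT,13.06,mg,report",
    "Galium aparine,GERMCHILL,none,category,expert_opinion"
  ))
  rec <- read_trait_table(path)
  expect_s3_class(rec, "trait_records")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$value_num[1], 6.64)
  expect_true(is.na(rec$value_num[3]))

  out <- tempfile(fileext = ".csv")
  write_trait_table(rec, out)
  rec2 <- read_trait_table(out)
  expect_equal(rec2$species, rec$species)
  expect_equal(rec2$field_code, rec$field_code)
  expect_equal(rec2$value, rec$value)
  expect_equal(rec2$units, rec$units)
  expect_equal(rec2$source_quality, rec$source_quality)

  # empty file with valid header -> empty collection
  empty <- make_table(character(0))
  expect_equal(nrow(read_trait_table(empty)), 0L)
})

test_that("schema violations are rejected with diagnostics", {
  # unknown code errors and names the legal codes
  bad_code <- make_table("Poa annua,HEIGHT,38,cm,peer_reviewed")
  err <- expect_error(read_trait_table(bad_code), class = "wf_validation_error")
  expect_match(conditionMessage(err), "HEIGHT")
  expect_match(conditionMessage(err), "COMPHEIGHT")
  expect_match(conditionMessage(err), "row 1")

  # missing mandatory column is a format error
  nohead <- tempfile(fileext = ".csv")
  writeLines(c("species,value", "x,1"), nohead)
  expect_error(read_trait_table(nohead), class = "wf_format_error")

  # positivity, categorical tokens, source quality
  expect_error(read_trait_table(make_table("x,SEEDWEIGHT,-1,mg,report")),
               class = "wf_validation_error")
  expect_error(read_trait_table(make_table("x,GERMCHILL,maybe,cat,report")),
               class = "wf_validation_error")
  expect_error(read_trait_table(make_table("x,SEEDWEIGHT,1,mg,blog")),
               class = "wf_validation_error")

  # non-strict mode drops the bad row with a warning
  mixed <- make_table(c("x,SEEDWEIGHT,1,mg,report", "x,HEIGHT,2,cm,report"))
  expect_warning(rec <- read_trait_table(mixed, strict = FALSE), "row 2")
  expect_equal(nrow(rec), 1L)

  # emergence calendars must close to 100
  months <- sprintf("x,EMCAL_%d,%g,%%,report", 1:12, c(rep(8, 11), 11))
  expect_error(read_trait_table(make_table(months)),
               class = "wf_validation_error")
  months_ok <- sprintf("x,EMCAL_%d,%g,%%,report", 1:12, c(rep(8, 11), 12))
  expect_equal(nrow(read_trait_table(make_table(months_ok))), 12L)
})

test_that("summarize_species matches brute-force statistics", {
  rows <- c(sprintf("Aa bb,GERMBASE,%g,degC,report", c(1, 2, 3, 4)),
            "Cc dd,SEEDWEIGHT,5.0,mg,report",
            sprintf("Aa bb,GERMCHILL,%s,cat,report", c("none", "none", "partial")))
  s <- summarize_species(read_trait_table(make_table(rows)))

  g <- s[s$species == "Aa bb" & s$field_code == "GERMBASE", ]
  expect_equal(g$mean, 2.5)
  expect_equal(g$median, 2.5)
  expect_equal(g$variability_pct, 400)
  expect_equal(g$n_records, 4L)

  single <- s[s$species == "Cc dd", ]
  expect_equal(unlist(single[c("mean", "median", "min", "max")]),
               c(mean = 5, median = 5, min = 5, max = 5))
  expect_equal(single$variability_pct, 100)

  cat_row <- s[s$field_code == "GERMCHILL", ]
  expect_equal(cat_row$modal_category, "none")
  expect_true(is.na(cat_row$mean))
})

test_that("summaries equal brute-force recomputation on generated fixtures", {
  rec <- generate_wtdb(generator_config(n_species = 8, seed = 42))
  s <- summarize_species(rec)
  for (k in sample(nrow(s), 10)) {
    v <- rec$value_num[rec$species == s$species[k] & rec$field_code == s$field_code[k]]
    expect_equal(s$mean[k], mean(v))
    expect_equal(s$median[k], median(v))
    expect_equal(s$min[k], min(v))
    expect_equal(s$max[k], max(v))
    if (min(v) > 0) expect_equal(s$variability_pct[k], 100 * max(v) / min(v))
  }
})

test_that("d5_from_comphyp inverts the hyperbolic yield-loss function", {
  expect_equal(d5_from_comphyp(0.5, 60), 5 / (0.5 * (1 - 5 / 60)))
  expect_equal(d5_from_comphyp(0.5, 60), 10.909, tolerance = 1e-4)
  expect_equal(d5_from_comphyp(0.05, 6), 600)
  expect_equal(d5_from_comphyp(0.5, Inf), 10)
  expect_error(d5_from_comphyp(0.5, 5), class = "wf_validation_error")
  expect_error(d5_from_comphyp(0, 60), class = "wf_validation_error")

  set.seed(11)
  i <- exp(runif(1000, log(0.01), log(30)))
  m <- runif(1000, 5 + 1e-3, 200)
  d5 <- d5_from_comphyp(i, m)
  expect_true(max(abs(yield_loss_hyperbolic(i, d5, m) - 5)) < 1e-9)
})

test_that("correlation_matrix handles identities, flags and recovery", {
  rec <- generate_wtdb(generator_config(n_species = 19, seed = 3))
  s <- summarize_species(rec)
  cm <- correlation_matrix(s, c("SEEDWEIGHT", "COMPHEIGHT", "FECUNDITY_2"))
  expect_equal(diag(cm$r), c(SEEDWEIGHT = 1, COMPHEIGHT = 1, FECUNDITY_2 = 1))
  expect_equal(cm$r, t(cm$r))

  # collinear and anti-collinear columns through a hand-built summary
  hand <- data.frame(
    species = rep(sprintf("s%d", 1:4), 3),
    field_code = rep(c("GERMBASE", "COMPHEIGHT", "SEEDCOAT"), each = 4),
    n_records = 1L, mean = c(1:4, 2 * (1:4), -(1:4)),
    median = NA, min = NA, max = NA, variability_pct = NA,
    modal_category = NA_character_
  )
  class(hand) <- c("species_trait_summary", "data.frame")
  cm2 <- correlation_matrix(hand, c("GERMBASE", "COMPHEIGHT", "SEEDCOAT"))
  expect_equal(cm2$r["GERMBASE", "COMPHEIGHT"], 1)
  expect_equal(cm2$r["GERMBASE", "SEEDCOAT"], -1)

  # zero-variance column flagged, not NaN
  hand$mean[hand$field_code == "SEEDCOAT"] <- 7
  cm3 <- correlation_matrix(hand, c("GERMBASE", "SEEDCOAT"))
  expect_true(is.na(cm3$r["GERMBASE", "SEEDCOAT"]))
  expect_equal(cm3$status["GERMBASE", "SEEDCOAT"], "zero_variance")

  # insufficient shared species flagged
  hand2 <- hand[hand$species %in% c("s1", "s2"), ]
  class(hand2) <- class(hand)
  cm4 <- correlation_matrix(hand2, c("GERMBASE", "COMPHEIGHT"))
  expect_equal(cm4$status["GERMBASE", "COMPHEIGHT"], "insufficient_n")
})

test_that("correlation recovery on a known r = 0.8 structure", {
  # brute-force oracle: build correlated pairs, push them through the long
  # record layout, and compare the matrix entry with cor() on the raw draws
  set.seed(19)
  n <- 19
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  df <- data.frame(
    species = rep(sprintf("Virt sp%02d", 1:n), 2),
    field_code = rep(c("GERMBASE", "FECUNDITY_2"), each = n),
    value = c(x, y), units = "u", source_quality = "report"
  )
  s <- summarize_species(as_trait_records(df))
  cm <- correlation_matrix(s, c("GERMBASE", "FECUNDITY_2"))
  expect_equal(cm$r["GERMBASE", "FECUNDITY_2"], cor(x, y))
  expect_equal(cm$n["GERMBASE", "FECUNDITY_2"], n)
  expect_gt(cm$r["GERMBASE", "FECUNDITY_2"], 0.5)
})

test_that("add_d5_summaries derives D5% from mean hyperbola parameters", {
  df <- data.frame(
    species = rep(c("A a", "B b", "C c"), each = 2),
    field_code = rep(c("COMPHYP_1", "COMPHYP_2"), 3),
    value = c(0.5, 60, 0.05, 6, 1, 4), # C c has m <= 5: skipped
    units = "u", source_quality = "report"
  )
  s <- add_d5_summaries(summarize_species(as_trait_records(df)))
  d5 <- s[s$field_code == "D5PCT", ]
  expect_equal(d5$species, c("A a", "B b"))
  expect_equal(d5$mean, c(d5_from_comphyp(0.5, 60), d5_from_comphyp(0.05, 6)))
})
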