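test_that("response CSVs are read, validated, and round-tripped", {
  design <- study_design(2, 2, 1, 3)
  path <- tempfile(fileext = ".csv")
  writeLines(c("person_id,w1_a1,w1_a2,w2_a1,w2_a2,w1_f1,w2_f1",
               "p1,0,1,1,1,2,3",
               "p2,1,0,0,1,1,2"), path)
  dat <- read_responses(path, design)
  expect_equal(length(dat$person_ids), 2)
  expect_equal(ncol(dat$ability) + ncol(dat$anxiety), 6)
  expect_equal(dat$ability[1, "w2_a1"], c(w2_a1 = 1L))

  out <- tempfile(fileext = ".csv")
  write_responses(dat, out)
  dat2 <- read_responses(out, design)
  expect_identical(dat2$ability, dat$ability)
  expect_identical(dat2$anxiety, dat$anxiety)
  expect_equal(as.character(dat2$person_ids), as.character(dat$person_ids))

  # out-of-range ability code names the offending cell
  writeLines(c("person_id,w1_a1,w1_a2,w2_a1,w2_a2,w1_f1,w2_f1",
               "p1,0,2,1,1,2,3"), path)
  expect_error(read_responses(path, design), class = "latsem_validation_error")
  expect_error(read_responses(path, design), "w1_a2")

  # blank cell violates the complete-case contract
  writeLines(c("person_id,w1_a1,w1_a2,w2_a1,w2_a2,w1_f1,w2_f1",
               "p1,0,1,1,1,,3"), path)
  expect_error(read_responses(path, design), class = "latsem_incomplete_error")

  # missing column is a format error
  writeLines(c("person_id,w1_a1,w1_a2,w2_a1,w2_a2,w1_f1",
               "p1,0,1,1,1,2"), path)
  expect_error(read_responses(path, design), class = "latsem_format_error")
})

test_that("ceiling filter applies both exclusion rules and is idempotent", {
  design <- study_design(7, 2, 0)
  perfect_at <- function(waves) {
    x <- rep(0L, 14)
    for (w in waves) x[(w - 1) * 2 + 1:2] <- 1L
    x
  }
  ability <- rbind(perfect_at(c(1, 3, 5, 7)),   # >= 4 perfect waves
                   perfect_at(c(2, 3, 4)),      # 3 in a row
                   perfect_at(c(1, 4, 7)),      # neither rule
                   perfect_at(integer(0)))
  dat <- response_matrix(design, ability, person_ids = c("a", "b", "c", "d"))
  res <- ceiling_filter(dat)
  expect_setequal(res$excluded$person_id, c("a", "b"))
  expect_equal(res$excluded$rule[res$excluded$person_id == "a"],
               "four_or_more_perfect")
  expect_equal(res$excluded$rule[res$excluded$person_id == "b"],
               "three_in_a_row")
  expect_setequal(res$data$person_ids, c("c", "d"))
  # idempotence
  res2 <- ceiling_filter(res$data)
  expect_equal(nrow(res2$excluded), 0)
  expect_equal(res2$data$person_ids, res$data$person_ids)
})

test_that("descriptives: consistencies, degenerate scales, exchangeability", {
  # two identical Likert items give alpha = 1
  design <- study_design(2, 2, 2, 5)
  set.seed(1)
  f <- matrix(sample(1:5, 40, replace = TRUE), 10, 4)
  f[, 2] <- f[, 1]; f[, 4] <- f[, 3]
  a <- matrix(rbinom(40, 1, 0.6), 10, 4)
  dat <- response_matrix(design, a, f)
  de <- descriptives(dat)
  alpha <- de$summary$consistency[de$summary$scale == "anxiety"]
  expect_equal(alpha, c(1, 1), tolerance = 1e-12)

  # constant wave sums give SD 0 and undefined consistency
  a0 <- matrix(rep(c(1L, 0L), each = 10), 10, 4)[, c(1, 3, 2, 4)]
  a0 <- cbind(a0[, 1:2], a0[, 1:2])
  dat0 <- response_matrix(design, a0, f)
  de0 <- descriptives(dat0)
  expect_equal(de0$summary$sd[1], 0)
  expect_true(is.na(de0$summary$consistency[1]))

  # KR-20 matches an independent transcription of the formula
  sc <- small_mixed_scenario(n = 300, seed = 11)
  datl <- generate(sc)
  del <- descriptives(datl)
  for (t in 1:3) {
    cols <- (t - 1) * 4 + 1:4
    expect_equal(del$summary$consistency[del$summary$scale == "ability" &
                                           del$summary$wave == t],
                 oracle_kr20(datl$ability[, cols]), tolerance = 1e-12)
  }
  expect_true(all(del$summary$consistency >= 0 &
                    del$summary$consistency <= 1, na.rm = TRUE))

  # permuting persons changes nothing
  perm <- sample(nrow(datl$ability))
  datp <- response_matrix(datl$design, datl$ability[perm, ],
                          datl$anxiety[perm, ],
                          person_ids = datl$person_ids[perm])
  dep <- descriptives(datp)
  expect_equal(dep$summary, del$summary)
  expect_equal(dep$correlations, del$correlations)
})
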