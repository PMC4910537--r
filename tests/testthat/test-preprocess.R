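make_diary <- function() {
  data.frame(
    individual_id = c("a", "a", "a", "b"),
    day_index = c(1, 2, 3, 1),
    day_type = c("weekday", "weekday", "weekend", "weekday"),
    food_item = c("apple", "pear", "apple", "bread"),
    amount = c(35, 35, 35, 70),
    stringsAsFactors = FALSE
  )
}

test_that("diary aggregation averages over the record length", {
  mapping <- data.frame(food_item = c("apple", "pear", "bread"),
                        group = c("fruit", "fruit", "cereal"),
                        stringsAsFactors = FALSE)
  X <- aggregate_to_groups(make_diary(), mapping, n_days = 7)
  expect_equal(X["a", "fruit"], 15)   # (35+35+35)/7
  expect_equal(X["b", "cereal"], 10)  # 70/7
  expect_equal(X["b", "fruit"], 0)
  # mass conservation: matrix x n_days equals diary totals
  expect_equal(sum(X) * 7, sum(make_diary()$amount))
})

test_that("unmapped food items raise a named error; roster adds zero rows", {
  mapping <- data.frame(food_item = c("apple", "pear"),
                        group = c("fruit", "fruit"))
  expect_error(aggregate_to_groups(make_diary(), mapping, 7), "bread")
  mapping2 <- rbind(mapping, data.frame(food_item = "bread", group = "cereal"))
  X <- aggregate_to_groups(make_diary(), mapping2, 7, roster = c("a", "b", "c"))
  expect_equal(rownames(X), c("a", "b", "c"))
  expect_equal(unname(X["c", ]), c(0, 0))
})

test_that("a 74-group mapping yields a 74-column matrix", {
  groups <- sprintf("grp%02d", 1:74)
  items <- paste0("item_", groups)
  mapping <- data.frame(food_item = items, group = groups)
  rec <- data.frame(individual_id = "a", day_index = 1, day_type = "weekday",
                    food_item = items, amount = 7)
  X <- aggregate_to_groups(rec, mapping, 7)
  expect_equal(ncol(X), 74)
  expect_equal(unname(X[1, ]), rep(1, 74))
})

test_that("rare-group filter drops below-threshold groups and is idempotent", {
  # 1000 individuals: groups at 9.9%, exactly 10% and 50% consumption rate
  n <- 1000
  X <- cbind(rare = c(rep(1, 99), rep(0, n - 99)),
             boundary = c(rep(1, 100), rep(0, n - 100)),
             common = c(rep(1, 500), rep(0, n - 500)))
  rownames(X) <- paste0("i", 1:n)
  f <- filter_rare_groups(X, 0.10)
  expect_equal(colnames(f$matrix), c("boundary", "common"))
  expect_equal(f$excluded$group, "rare")
  f2 <- filter_rare_groups(f$matrix, 0.10)
  expect_equal(f2$matrix, f$matrix)
  expect_equal(nrow(f2$excluded), 0)
})

test_that("a 74-group fixture with 8 rare groups keeps 66", {
  set.seed(31)
  n <- 400
  rates <- c(runif(66, 0.15, 0.95), runif(8, 0.01, 0.09))
  X <- sapply(rates, function(r) ifelse(runif(n) < r, runif(n, 10, 100), 0))
  colnames(X) <- sprintf("g%02d", 1:74)
  rownames(X) <- paste0("i", 1:n)
  f <- filter_rare_groups(X, 0.10)
  expect_equal(ncol(f$matrix), 66)
  expect_equal(nrow(f$excluded), 8)
  expect_equal(colnames(f$matrix), colnames(X)[1:66])  # order preserved
})

test_that("low-energy exclusion applies the configurable BMR rule", {
  cov <- data.frame(individual_id = c("a", "b", "c"),
                    sex = c("male", "female", "male"),
                    age = c(25, 40, 70), body_weight_kg = c(75, 62, 80))
  tei <- c(a = 0, b = 3000, c = 900)
  r <- exclude_low_energy(tei, cov)
  expect_true("a" %in% r$excluded)      # zero intake always excluded
  expect_true("b" %in% r$kept)
  bmr_c <- schofield_bmr("male", 70, 80)
  expect_equal("c" %in% r$excluded, unname(900 < 0.45 * bmr_c))
  expect_equal(r$report$n_excluded, length(r$excluded))
  expect_error(exclude_low_energy(c(a = NA_real_), cov), "missing")
})

test_that("an exclusion fixture tuned to 0.9% reports that fraction", {
  set.seed(12)
  n <- 1000
  cov <- data.frame(individual_id = paste0("i", 1:n),
                    sex = sample(c("male", "female"), n, TRUE),
                    age = runif(n, 18, 79),
                    body_weight_kg = runif(n, 50, 95))
  bmr <- schofield_bmr(cov$sex, cov$age, cov$body_weight_kg)
  tei <- 1.4 * bmr
  low <- sample(n, 9)                  # plant 9/1000 below the cut-off
  tei[low] <- 0.3 * bmr[low]
  names(tei) <- cov$individual_id
  r <- exclude_low_energy(tei, cov)
  expect_equal(r$report$fraction_excluded, 0.009)
})

test_that("under-reporter flags follow the Goldberg cut-off and only annotate", {
  cov <- data.frame(individual_id = c("a", "b"),
                    sex = c("male", "female"),
                    age = c(30, 30), body_weight_kg = c(70, 60))
  bmr <- schofield_bmr(cov$sex, cov$age, cov$body_weight_kg)
  tei <- c(a = 0.5 * bmr[1], b = 2.0 * bmr[2])
  fl <- flag_under_reporters(tei, cov, cutoff = 1.05)
  expect_identical(unname(fl), c(TRUE, FALSE))

  # fixture planted at 26.9% under-reporters
  set.seed(13)
  n <- 1000
  cov <- data.frame(individual_id = paste0("i", 1:n),
                    sex = sample(c("male", "female"), n, TRUE),
                    age = runif(n, 18, 79),
                    body_weight_kg = runif(n, 50, 95))
  bmr <- schofield_bmr(cov$sex, cov$age, cov$body_weight_kg)
  ratio <- rep(1.5, n)
  ratio[sample(n, 269)] <- 0.8
  tei <- ratio * bmr
  names(tei) <- cov$individual_id
  expect_equal(mean(flag_under_reporters(tei, cov)), 0.269, tolerance = 0.01)
})
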