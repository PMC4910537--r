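toy_composition <- function() {
  nutr <- mar_nutrients()
  comp <- data.frame(food_group = c("bread", "fish", "water"),
                     beverage = c(FALSE, FALSE, TRUE),
                     dds_group = c("cereals", "meat", NA),
                     energy_kcal = c(250, 120, 0),
                     stringsAsFactors = FALSE)
  for (nm in nutr) comp[[nm]] <- c(2, 5, 0)
  comp$vit_c_mg <- c(10, 0, 0)
  comp
}

test_that("nutrient intakes follow the per-100g convention", {
  comp <- toy_composition()
  X <- matrix(c(100, 0, 0), 1, 3,
              dimnames = list("a", c("bread", "fish", "water")))
  ni <- nutrient_intakes(X, comp)
  expect_equal(unname(ni$intakes["a", "vit_c_mg"]), 10)
  expect_equal(unname(ni$tei["a"]), 250)
  expect_equal(unname(nutrient_intakes(X * 0, comp)$intakes["a", ]),
               rep(0, ncol(ni$intakes)))
  # linearity and a two-food hand computation
  X2 <- matrix(c(150, 80, 500), 1, 3,
               dimnames = list("a", c("bread", "fish", "water")))
  ni2 <- nutrient_intakes(X2, comp)
  expect_equal(unname(ni2$intakes["a", "protein_g"]),
               1.5 * 2 + 0.8 * 5)
  expect_equal(nutrient_intakes(3 * X2, comp)$intakes, 3 * ni2$intakes)
  expect_error(nutrient_intakes(
    matrix(1, 1, 1, dimnames = list("a", "unknown")), comp), "unknown")
})

test_that("MAR honours truncation so surplus cannot compensate deficit", {
  nutr <- mar_nutrients()
  rda <- data.frame(sex = rep(c("male", "female"), 5),
                    age_band = rep(c("18-24", "25-34", "35-49", "50-64", "65+"),
                                   each = 2))
  for (nm in nutr) rda[[nm]] <- 10
  sex <- c("male", "male", "female")
  age <- c(30, 30, 70)

  M <- matrix(20, 3, 20, dimnames = list(NULL, nutr))   # all >= RDA
  expect_equal(mar(M, rda, sex, age), rep(100, 3))
  expect_equal(mar(M / 4, rda, sex, age), rep(50, 3))   # all at half RDA
  Mm <- M; Mm[, 1:10] <- 0                              # 10 at 2xRDA, 10 at 0
  expect_equal(mar(Mm, rda, sex, age), rep(50, 3))
  # monotone non-decreasing in any intake
  Mup <- M / 4; Mup[, 3] <- Mup[, 3] + 1
  expect_true(all(mar(Mup, rda, sex, age) >= mar(M / 4, rda, sex, age)))
  rda0 <- rda; rda0$protein_g <- 0
  expect_error(mar(M, rda0, sex, age), "RDA")
})

test_that("energy density excludes beverages and flags empty diets", {
  comp <- toy_composition()
  cols <- c("bread", "fish", "water")
  X <- matrix(c(100, 0, 0), 1, 3, dimnames = list("a", cols))
  comp2 <- comp; comp2$energy_kcal <- c(200, 120, 0)
  expect_equal(unname(energy_density(X, comp2)), 2.0)   # 200 kcal / 100 g
  # adding half a litre of water changes nothing
  Xw <- X; Xw[1, "water"] <- 500
  expect_equal(energy_density(Xw, comp2), energy_density(X, comp2))
  # hand-computed three-food mix
  X3 <- matrix(c(150, 80, 300), 1, 3, dimnames = list("a", cols))
  expect_equal(unname(energy_density(X3, comp2)),
               (1.5 * 200 + 0.8 * 120) / 230)
  # beverage-only diet is undefined, not zero
  Xb <- matrix(c(0, 0, 400), 1, 3, dimnames = list("a", cols))
  expect_true(is.na(energy_density(Xb, comp2)))
})

test_that("DDS counts macro groups at the 30 g boundary over 3 sampled days", {
  mapping <- data.frame(
    food_group = c("milk", "beef", "rice", "apple", "carrot", "oil"),
    dds_group = c("dairy", "meat", "cereals", "fruits", "vegetables", NA),
    stringsAsFactors = FALSE)
  base_days <- data.frame(individual_id = "a", day_index = 1:7,
                          day_type = c(rep("weekday", 5), rep("weekend", 2)),
                          food_group = "oil", amount = 1e-9)
  rich <- do.call(rbind, lapply(1:7, function(d) {
    data.frame(individual_id = "a", day_index = d,
               day_type = if (d <= 5) "weekday" else "weekend",
               food_group = c("milk", "beef", "rice", "apple", "carrot"),
               amount = 30)
  }))
  expect_equal(unname(dds(rich, mapping, seed = 1)), 5L)
  expect_equal(unname(dds(base_days, mapping, seed = 1)), 0L)

  # 29 g of fruit in total, >= 30 g elsewhere -> 4
  diary <- data.frame(individual_id = "a", day_index = rep(1:7, each = 5),
                      day_type = rep(c(rep("weekday", 5), rep("weekend", 2))[rep(1:7, each = 5)] , 1),
                      food_group = rep(c("milk", "beef", "rice", "apple", "carrot"), 7),
                      amount = rep(c(30, 30, 30, 29 / 7 / 3, 30), 7))
  # fruit: 29/21 g per day -> under 30 g over any 3 days
  expect_equal(unname(dds(diary, mapping, seed = 2)), 4L)

  # deterministic given the seed, always within 0..5
  sc1 <- dds(rich, mapping, seed = 9)
  sc2 <- dds(rich, mapping, seed = 9)
  expect_identical(sc1, sc2)
  expect_true(all(sc1 %in% 0:5))

  # missing weekend days are an error
  wk_only <- rich[rich$day_index <= 5, ]
  expect_error(dds(wk_only, mapping, seed = 1), "weekend")
})

test_that("group-mean comparison matches an unweighted oracle at equal weights", {
  set.seed(51)
  n <- 200
  lab <- sample(1:3, n, TRUE)
  cov <- data.frame(age = runif(n, 18, 80))
  y <- rnorm(n) + 0.03 * cov$age + 1.2 * (lab == 2)
  r <- compare_group_means(y, lab, cov, weights = NULL)
  # oracle: plain lm with treatment coding; contrast vs share-weighted mean
  age <- cov$age
  fit <- lm(y ~ 0 + factor(lab) + age)
  shares <- as.numeric(table(lab) / n)
  bet <- coef(fit)[1:3]
  expect_equal(r$diff, unname(bet - sum(shares * bet)), tolerance = 1e-8)
  expect_equal(r$flag[2], "higher")
})

test_that("a planted shift is flagged in the right direction", {
  set.seed(52)
  n <- 1500
  lab <- sample(1:4, n, TRUE)
  y <- rnorm(n) + 1 * (lab == 3) - 1 * (lab == 4)
  r <- compare_group_means(y, lab, NULL, NULL)
  expect_equal(r$flag[3], "higher")
  expect_equal(r$flag[4], "lower")
})

test_that("collinear covariates produce a named singular-fit error", {
  set.seed(53)
  n <- 60
  lab <- sample(1:2, n, TRUE)
  cov <- data.frame(a = rnorm(n))
  cov$b <- 2 * cov$a
  expect_error(compare_group_means(rnorm(n), lab, cov), "collinear")
})
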