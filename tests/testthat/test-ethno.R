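# Ethnobiological tabulations: effort, composition, correspondence ANOVA.

test_that("effort_table reproduces the published nine-fisher tabulation", {
  r <- study_effort_logbook()
  et <- effort_table(r)
  expect_equal(et$sightings_n[et$fisher_id == "F1"], 65)
  expect_equal(et$effort_days[et$fisher_id == "F1"], 16)
  expect_equal(et$landing_port[et$fisher_id == "F1"], "Ponta de Matos")
  expect_equal(et$sightings_n[et$fisher_id == "total"], 218)
  expect_equal(et$sightings_n[match(paste0("F", 1:9), et$fisher_id)],
               c(65, 7, 61, 5, 22, 7, 30, 19, 2))
  # totals are invariant to record order
  et2 <- effort_table(r[sample(nrow(r)), ])
  expect_equal(et2$sightings_n[et2$fisher_id == "total"], 218)

  empty <- effort_table(r[0, ])
  expect_equal(empty$sightings_n, 0)

  # effort from distinct record dates when a fisher has no trips
  one <- r[r$fisher_id == "F5", ][1:6, ]
  one$date <- as.Date("2018-07-02") + c(0, 0, 1, 1, 2, 2)
  expect_equal(effort_table(one)$effort_days[1], 3)
})

test_that("species composition partitions records and uses the stated denominators", {
  comp <- species_composition(study_effort_logbook())
  expect_equal(comp$n_records, 218)
  expect_equal(comp$n_identified, 106)
  expect_equal(comp$species$n[comp$species$species == "Chelonia mydas"], 88)
  expect_equal(comp$species$n[comp$species$species == "Caretta caretta"], 11)
  expect_equal(comp$species$n[comp$species$species == "Eretmochelys imbricata"], 7)
  # 112 / 218 = 51.376%; published rounding prints 51.37
  expect_lt(abs(comp$pct_unidentified - 51.37), 0.011)
  expect_equal(sum(comp$species$pct_of_identified), 100, tolerance = 0.02)

  allun <- study_effort_logbook(); allun$species <- NA_character_
  expect_equal(species_composition(allun)$pct_unidentified, 100)
  single <- study_effort_logbook()[120, ]  # one identified record
  cs <- species_composition(single)
  expect_equal(cs$species$pct_of_identified, 100)
})

test_that("the ANOVA F equals the classical sums-of-squares ratio", {
  # textbook three-group layout
  y <- c(18, 22, 21, 17, 24, 26, 23, 25, 30, 29, 28, 31)
  gr <- rep(c("A", "B", "C"), each = 4)
  f_oracle <- oracle_anova_F(y, gr)
  f_aov <- stats::anova(stats::aov(y ~ factor(gr)))[["F value"]][1]
  expect_equal(f_aov, f_oracle, tolerance = 1e-10)

  # the module's path on record-level indicators agrees with the oracle too
  rec <- data.frame(
    fisher_id = rep(paste0("F", 1:6), each = 10),
    community = rep(c("Ponta de Matos", "Penha", "Jacumã"), each = 20),
    folk_name = "tartaruga-verde",
    species = rep(rep(c("Chelonia mydas", "Caretta caretta"), times = c(7, 3)), 6),
    stringsAsFactors = FALSE
  )
  res <- correspondence_anova(rec, unit = "record")
  expect_equal(res$F,
               oracle_anova_F(res$data$y, res$data$group), tolerance = 1e-10)
})

test_that("identical constant groups give F = 0 and p = 1 explicitly", {
  rec <- data.frame(
    fisher_id = rep(paste0("F", 1:6), each = 4),
    community = rep(c("Penha", "Jacumã"), each = 12),
    folk_name = "tartaruga-verde", species = "Chelonia mydas",
    stringsAsFactors = FALSE
  )
  res <- correspondence_anova(rec)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$tukey$p_adj == 1))
})

test_that("a community with depressed correspondence drives the smallest Tukey p-values", {
  set.seed(77)
  mk <- function(comm, fishers, p_match, n = 12) {
    do.call(rbind, lapply(fishers, function(f) {
      match <- runif(n) < p_match
      data.frame(fisher_id = f, community = comm,
                 folk_name = "tartaruga-verde",
                 species = ifelse(match, "Chelonia mydas", "Caretta caretta"),
                 stringsAsFactors = FALSE)
    }))
  }
  rec <- rbind(mk("Ponta de Matos", c("F1", "F2", "F3"), 0.75),
               mk("Penha", c("F4", "F5", "F6"), 0.75),
               mk("Jacumã", c("F7", "F8", "F9"), 0.45))
  res <- correspondence_anova(rec)
  expect_lt(res$proportions[["Jacumã"]], res$proportions[["Penha"]])
  jac <- grepl("Jacumã", res$tukey$contrast)
  expect_lt(max(res$tukey$p_adj[jac]), min(res$tukey$p_adj[!jac]))
  # "turtle" records are excluded from the test
  rec2 <- rbind(rec, data.frame(fisher_id = "F1", community = "Ponta de Matos",
                                folk_name = "turtle", species = NA_character_,
                                stringsAsFactors = FALSE))
  expect_equal(correspondence_anova(rec2)$F, res$F)

  expect_error(correspondence_anova(rec[rec$community == "Penha", ]),
               "2 communities")
  expect_error(correspondence_anova(rec[rec$fisher_id %in% c("F1", "F4", "F7"), ]),
               "fewer than 2")
})
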