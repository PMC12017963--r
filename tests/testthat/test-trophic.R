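tax_fixture <- function() {
  tibble::tibble(
    taxon_id = c("A", "B", "C", "D"),
    lineage = c(
      "Eukaryota;Sg;Div1;Cl1;Or1;Fam1;GenX;GenX sp1",
      "Eukaryota;Sg;Div1;Cl1;Or1;Fam1;GenX;GenX sp2",
      "Eukaryota;Sg;Div2;Cl2;Or2;Fam2;GenY;GenY sp1",
      "Eukaryota;Sg;Div2;Cl2;Or2;Fam2;GenZ;GenZ sp1"
    ),
    db_trophic = c("mixotroph", "mixotroph", "autotroph", NA)
  )
}

test_that("manual overrides beat the database annotation", {
  ov <- tibble::tibble(lineage_name = "GenX", rank = "genus",
                       mode = "heterotroph")
  ann <- annotate_trophic(tax_fixture(), ov)
  expect_equal(ann$mode[ann$taxon_id == "A"], "heterotroph")
  expect_equal(ann$provenance[ann$taxon_id == "A"], "manual")
  expect_equal(ann$mode[ann$taxon_id == "C"], "autotroph")
  expect_equal(ann$provenance[ann$taxon_id == "C"], "db")
})

test_that("taxa without any source are unknown and flagged", {
  ann <- annotate_trophic(tax_fixture())
  expect_equal(ann$mode[ann$taxon_id == "D"], "unknown")
  expect_equal(ann$provenance[ann$taxon_id == "D"], "unknown")
})

test_that("the most specific override rank wins", {
  ov <- tibble::tibble(
    lineage_name = c("GenX", "GenX sp1"),
    rank = c("genus", "species"),
    mode = c("mixotroph", "autotroph")
  )
  ann <- annotate_trophic(tax_fixture(), ov)
  expect_equal(ann$mode[ann$taxon_id == "A"], "autotroph") # species wins
  expect_equal(ann$mode[ann$taxon_id == "B"], "mixotroph") # genus only
})

test_that("annotation is idempotent and override-order independent", {
  ov <- tibble::tibble(
    lineage_name = c("GenX", "GenX sp1", "Fam2"),
    rank = c("genus", "species", "family"),
    mode = c("mixotroph", "autotroph", "heterotroph")
  )
  base <- annotate_trophic(tax_fixture(), ov)
  for (k in 1:5) {
    set.seed(k)
    shuffled <- ov[sample(nrow(ov)), ]
    expect_equal(annotate_trophic(tax_fixture(), shuffled), base)
  }
})

test_that("invalid override vocabulary or rank errors", {
  expect_error(
    annotate_trophic(tax_fixture(),
                     tibble::tibble(lineage_name = "GenX", rank = "genus",
                                    mode = "carnivore")),
    "vocabulary"
  )
  expect_error(
    annotate_trophic(tax_fixture(),
                     tibble::tibble(lineage_name = "GenX", rank = "tribe",
                                    mode = "autotroph")),
    "rank"
  )
})

profile_fixture <- function() {
  counts <- matrix(
    c(50, 25, 25,
      80, 80, 40),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("auto1", "het1", "mix1"))
  )
  m <- tiny_md(counts)
  m$metadata$season <- c("winter", "winter")
  modes <- tibble::tibble(taxon_id = c("auto1", "het1", "mix1"),
                          mode = c("autotroph", "heterotroph", "mixotroph"))
  list(m = m, modes = modes)
}

test_that("per-sample proportions and competitiveness ratios are exact", {
  fx <- profile_fixture()
  pr <- trophic_profile(fx$m, fx$modes)
  s1 <- pr$samples[pr$samples$sample_id == "s1", ]
  expect_equal(c(s1$autotroph_prop, s1$heterotroph_prop, s1$mixotroph_prop),
               c(0.5, 0.25, 0.25))
  expect_equal(s1$auto_mixo_ratio, 2)
  expect_equal(s1$hete_mixo_ratio, 1)
})

test_that("zero mixotroph reads flag the ratio as undefined", {
  fx <- profile_fixture()
  fx$m$counts[, "mix1"] <- 0L
  pr <- trophic_profile(fx$m, fx$modes)
  expect_true(all(is.na(pr$samples$auto_mixo_ratio)))
  expect_true(all(pr$samples$flag == "ratio_undefined"))
})

test_that("seasonal aggregation pools reads before taking proportions", {
  fx <- profile_fixture()
  pr <- trophic_profile(fx$m, fx$modes)
  season <- pr$by_season
  # pooled: auto 130, het 105, mix 65 of 300 -- not the mean of proportions
  expect_equal(season$autotroph_prop, 130 / 300)
  expect_equal(season$heterotroph_prop, 105 / 300)
  expect_equal(season$mixotroph_prop, 65 / 300)
  mean_of_props <- mean(pr$samples$autotroph_prop)
  expect_false(isTRUE(all.equal(season$autotroph_prop, mean_of_props)))
})

test_that("unknown taxa are excluded before renormalisation", {
  counts <- matrix(c(10, 10, 10, 70), nrow = 1,
                   dimnames = list("s1", c("a", "h", "m", "u")))
  m <- tiny_md(counts)
  modes <- tibble::tibble(
    taxon_id = c("a", "h", "m", "u"),
    mode = c("autotroph", "heterotroph", "mixotroph", "unknown")
  )
  pr <- trophic_profile(m, modes)
  expect_equal(pr$samples$autotroph_prop, 1 / 3)
})

test_that("samples with no annotated core reads are flagged NA", {
  counts <- matrix(c(0, 5), nrow = 2,
                   dimnames = list(c("s1", "s2"), "m"))
  m <- tiny_md(counts)
  modes <- tibble::tibble(taxon_id = "m", mode = "mixotroph")
  expect_warning(pr <- trophic_profile(m, modes), "zero annotated")
  expect_true(is.na(pr$samples$mixotroph_prop[1]))
  expect_equal(pr$samples$flag[1], "no_annotated_reads")
})

test_that("core taxa outside the community are rejected", {
  fx <- profile_fixture()
  expect_error(trophic_profile(fx$m, fx$modes, core = c("auto1", "ghost")),
               "ghost")
})
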