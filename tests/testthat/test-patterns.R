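# layout with known regional structure for pattern tests
pattern_layout <- function(n = 16, seed = 2) make_sensor_layout(n, seed)

cm_from_edges <- function(lay, edges) {
  n <- length(lay$channel_ids)
  w <- matrix(0, n, n, dimnames = list(lay$channel_ids, lay$channel_ids))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  }
  connectivity_matrix(w, band = "theta")
}

test_that("a single negative bilateral-occipital edge sets only that flag", {
  lay <- pattern_layout()
  oL <- which(lay$regions == "occipital_L")[1]
  oR <- which(lay$regions == "occipital_R")[1]
  cm <- cm_from_edges(lay, list(list(oL, oR, -0.8)))
  pat <- classify_pattern(apply_threshold(cm, 0.5), lay)
  expect_true(pat$inhibitory[pat$roi == "occipital_bilateral"])
  expect_false(any(pat$excitatory))
  expect_equal(sum(pat$inhibitory), 1)
})

test_that("planted frontal positive edges show as frontal excitatory", {
  lay <- pattern_layout()
  fr <- which(lay$regions == "frontal")
  skip_if(length(fr) < 2)
  cm <- cm_from_edges(lay, list(list(fr[1], fr[2], 0.9)))
  pat <- classify_pattern(apply_threshold(cm, 0.5), lay)
  expect_true(pat$excitatory[pat$roi == "frontal"])
  expect_false(pat$inhibitory[pat$roi == "frontal"])
})

test_that("an empty edge set yields an all-false pattern", {
  lay <- pattern_layout()
  cm <- cm_from_edges(lay, list())
  pat <- classify_pattern(apply_threshold(cm, 0.5), lay)
  expect_false(any(pat$excitatory))
  expect_false(any(pat$inhibitory))
})

test_that("min_edges requires the stated number of suprathreshold edges", {
  lay <- pattern_layout()
  fr <- which(lay$regions == "frontal")
  skip_if(length(fr) < 3)
  cm <- cm_from_edges(lay, list(list(fr[1], fr[2], 0.9)))
  net <- apply_threshold(cm, 0.5)
  expect_true(classify_pattern(net, lay, 1)$excitatory[
    classify_pattern(net, lay, 1)$roi == "frontal"])
  expect_false(classify_pattern(net, lay, 2)$excitatory[
    classify_pattern(net, lay, 2)$roi == "frontal"])
  cm2 <- cm_from_edges(lay, list(list(fr[1], fr[2], 0.9),
                                 list(fr[1], fr[3], 0.7)))
  expect_true(classify_pattern(apply_threshold(cm2, 0.5), lay, 2)$excitatory[1])
})

test_that("raising tau never turns a pattern flag on", {
  lay <- pattern_layout(20, seed = 5)
  set.seed(6)
  n <- 20
  m <- matrix(runif(n * n, -1, 1), n)
  w <- (m + t(m)) / 2; diag(w) <- 0
  dimnames(w) <- list(lay$channel_ids, lay$channel_ids)
  cm <- connectivity_matrix(w)
  lowtau <- classify_pattern(apply_threshold(cm, 0.3), lay)
  hightau <- classify_pattern(apply_threshold(cm, 0.6), lay)
  expect_true(all(lowtau$excitatory | !hightau$excitatory))
  expect_true(all(lowtau$inhibitory | !hightau$inhibitory))
})

test_that("patterns are local to the regions of interest", {
  lay <- pattern_layout(24, seed = 7)
  roi_chans <- which(lay$regions %in% c("frontal", "temporal_L",
                                        "temporal_R", "occipital_L",
                                        "occipital_R"))
  skip_if(length(roi_chans) < 8)
  set.seed(8)
  n <- 24
  m <- matrix(runif(n * n, -1, 1), n)
  w <- (m + t(m)) / 2; diag(w) <- 0
  dimnames(w) <- list(lay$channel_ids, lay$channel_ids)
  full <- classify_pattern(
    apply_threshold(connectivity_matrix(w), 0.5), lay)
  sub <- structure(list(
    channel_ids = lay$channel_ids[roi_chans],
    positions = lay$positions[roi_chans, , drop = FALSE],
    regions = lay$regions[roi_chans]), class = "sensor_layout")
  wsub <- w[roi_chans, roi_chans]
  cut <- classify_pattern(
    apply_threshold(connectivity_matrix(wsub), 0.5), sub)
  expect_equal(cut$excitatory, full$excitatory)
  expect_equal(cut$inhibitory, full$inhibitory)
})

test_that("mismatched channel ids are rejected", {
  lay <- pattern_layout()
  other <- pattern_layout(17, seed = 3)
  cm <- cm_from_edges(lay, list())
  expect_error(classify_pattern(apply_threshold(cm, 0.5), other),
               "channel ids")
})

test_that("contour export writes a faithful edge manifest", {
  lay <- pattern_layout(12, seed = 4)
  i <- which(lay$regions == "frontal")[1]
  j <- which(lay$regions == "occipital_L")[1]
  k <- which(lay$regions == "temporal_L")[1]
  cm <- cm_from_edges(lay, list(list(i, j, 0.9), list(j, k, -0.7)))
  path <- tempfile(fileext = ".pdf")
  out <- export_contour_map(cm, lay, 0.5, path)
  expect_true(file.exists(path))
  man <- read.table(out$manifest, header = TRUE, sep = "\t")
  expect_equal(nrow(man), 2)
  expect_setequal(man$sign, c(1, -1))
  # threshold above every |w|: empty manifest
  out2 <- export_contour_map(cm, lay, 0.95, tempfile(fileext = ".pdf"))
  expect_equal(nrow(read.table(out2$manifest, header = TRUE, sep = "\t")), 0)
  # determinism of the manifest
  p3 <- tempfile(fileext = ".pdf")
  p4 <- tempfile(fileext = ".pdf")
  export_contour_map(cm, lay, 0.5, p3)
  export_contour_map(cm, lay, 0.5, p4)
  expect_identical(readLines(paste0(p3, ".manifest.tsv")),
                   readLines(paste0(p4, ".manifest.tsv")))
})
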