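# Four-case study workflow.

test_that("the default study emits four simulations and two comparison reports", {
  out <- tempfile("study")
  res <- suppressMessages(runStudy(studyConfig(seed = 1), outDir = out))
  expect_length(res$results, 4)
  expect_named(res$results, c("complex_physiological", "trimmed_physiological",
                              "complex_pathological", "trimmed_pathological"))
  expect_length(res$reports, 2)
  expect_s4_class(res$reports$physiological, "ComparisonReport")
  # pathological cases carry the two sacs at the left and right MCA
  for (nm in c("complex_pathological", "trimmed_pathological")) {
    nd <- networkNodes(res$networks[[nm]])
    expect_setequal(nd$label[nd$kind == "aneurysm_sac"], c("IA-A", "IA-B"))
  }
  # artifacts on disk, with a resolved config and content-hash manifest
  expect_true(file.exists(file.path(out, "config.json")))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "run.log")))
  expect_equal(sum(grepl("^result_", list.files(out))), 4)
  expect_equal(sum(grepl("^comparison_", list.files(out))), 2)
})

test_that("a study re-run with the same config is bit-identical", {
  cfg <- studyConfig(seed = 5, nOutlets = 16, keep = 6, skipImaging = TRUE,
                     solver = solverConfig(cycles = 2))
  r1 <- suppressMessages(runStudy(cfg, outDir = tempfile()))
  r2 <- suppressMessages(runStudy(cfg, outDir = tempfile()))
  m1 <- r1$manifest[r1$manifest$file != "config.json", ]
  m2 <- r2$manifest[r2$manifest$file != "config.json", ]
  expect_equal(m1$md5[order(m1$file)], m2$md5[order(m2$file)])
})

test_that("changing the seed changes the phantom but all invariants still hold", {
  cfg <- studyConfig(seed = 11, nOutlets = 12, keep = 6, skipImaging = TRUE,
                     solver = solverConfig(cycles = 1))
  res <- suppressMessages(runStudy(cfg, outDir = tempfile()))
  cfg2 <- studyConfig(seed = 12, nOutlets = 12, keep = 6, skipImaging = TRUE,
                      solver = solverConfig(cycles = 1))
  res2 <- suppressMessages(runStudy(cfg2, outDir = tempfile()))
  expect_false(identical(networkNodes(res$networks$complex_physiological),
                         networkNodes(res2$networks$complex_physiological)))
  for (r in c(res$results, res2$results)) {
    expect_true(validObject(r@network))
    expect_lt(r@residual, 1e-10 * max(abs(edgeFlows(r))))
  }
})

test_that("template-direct and image-roundtrip networks give comparable velocities", {
  r1 <- suppressMessages(runStudy(studyConfig(seed = 1, skipImaging = TRUE),
                                  outDir = tempfile()))
  r2 <- suppressMessages(runStudy(studyConfig(seed = 1, skipImaging = FALSE),
                                  outDir = tempfile()))
  p1 <- r1$metrics$complex_physiological@paths
  p2 <- r2$metrics$complex_physiological@paths
  common <- intersect(names(p1), names(p2))
  expect_gte(length(common), 4)
  for (p in common) {
    v1 <- mean(p1[[p]]$velocity_m_s)
    v2 <- mean(p2[[p]]$velocity_m_s)
    expect_lt(abs(v1 - v2) / v1, 0.10)
  }
})
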