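test_that("Slicer markups JSON round-trips a hand-written fiducial file", {
  path <- withr::local_tempfile(fileext = ".mrk.json")
  write_mrk_json(path, list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 labels = c("a", "b", "c"))
  cfg <- read_slicer_markups(path)
  expect_s3_class(cfg, "landmark_config")
  expect_equal(nrow(cfg$coords), 3L)
  expect_equal(unname(cfg$coords),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(cfg$labels, c("a", "b", "c"))
  expect_false(any(cfg$missing))
})

test_that("FCSV rows with blank coordinates are flagged missing", {
  path <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c(
    "# Markups fiducial file version = 5.8",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    "1,0.0,0.0,0.0,0,0,0,1,1,1,0,lmA,,",
    "2,,,,0,0,0,1,1,1,0,lmB,,",
    "3,2.5,1.0,-3.0,0,0,0,1,1,1,0,lmC,,"), path)
  cfg <- read_slicer_markups(path)
  expect_equal(cfg$missing, c(FALSE, TRUE, FALSE))
  expect_equal(cfg$labels, c("lmA", "lmB", "lmC"))
  expect_true(all(is.na(cfg$coords[2, ])))
  expect_equal(unname(cfg$coords[3, ]), c(2.5, 1, -3))
})

test_that("duplicate landmark labels are rejected at parse time", {
  path <- withr::local_tempfile(fileext = ".mrk.json")
  write_mrk_json(path, list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 labels = c("a", "a", "c"))
  expect_error(read_slicer_markups(path), "duplicate")
})

test_that("the simulated cranial template has the bilateral 54 + 54 + 12 structure", {
  sim <- simulate_landmarks(landmark_sim_params(
    groups = list(list(name = "A", n = 1, effect = 0)), missing_rate = 0, seed = 7))
  labs <- sim$dataset$labels
  expect_length(labs, 120L)
  expect_equal(sum(startsWith(labs, "L")), 54L)
  expect_equal(sum(startsWith(labs, "R")), 54L)
  expect_equal(sum(startsWith(labs, "M")), 12L)
  # and a written markups file reads back with the same template
  path <- withr::local_tempfile(fileext = ".mrk.json")
  coords <- sim$dataset$configurations[[1]]$coords
  write_mrk_json(path, lapply(seq_len(nrow(coords)), function(i) unname(coords[i, ])),
                 labels = labs)
  cfg <- read_slicer_markups(path)
  expect_equal(nrow(cfg$coords), 120L)
  expect_equal(cfg$labels, labs)
})

test_that("TPS files parse per record and survive a write/read round trip", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0.5 1", "ID=tri"), path)
  recs <- read_tps_file(path)
  expect_length(recs, 1L)
  expect_equal(ncol(recs[[1]]$coords), 2L)
  expect_equal(recs[[1]]$specimen_id, "tri")
  expect_equal(unname(recs[[1]]$coords), rbind(c(0, 0), c(1, 0), c(0.5, 1)))

  # round trip in 3D with awkward coordinates
  set.seed(3)
  cfgs <- lapply(1:3, function(i)
    landmark_config(matrix(rnorm(15) * 10^runif(1, -3, 3), 5, 3),
                    specimen_id = paste0("spec", i)))
  out <- withr::local_tempfile(fileext = ".tps")
  write_tps(cfgs, out)
  back <- read_tps_file(out)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(unname(back[[i]]$coords), unname(cfgs[[i]]$coords), tolerance = 1e-9)
    expect_equal(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
  }

  # two-record 3D file matches an independent line-by-line parse
  lines <- readLines(out)
  hdr <- grep("^LM3=", lines)
  manual <- do.call(rbind, lapply(strsplit(lines[(hdr[2] + 1):(hdr[2] + 5)], " "),
                                  as.numeric))
  expect_equal(unname(back[[2]]$coords), manual, tolerance = 1e-12)
})

test_that("TPS header/row count mismatch is a parse error", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=4", "0 0", "1 0", "0.5 1", "ID=short"), path)
  expect_error(read_tps_file(path), "expected")
})

test_that("assemble_dataset validates labels, metadata and missing counts", {
  toy <- toy_symmetric_config()
  cfg1 <- landmark_config(toy$coords, specimen_id = "s1")
  cfg2 <- landmark_config(toy$coords + 0.1, specimen_id = "s2")
  md <- data.frame(specimen_id = c("s1", "s2"), species = "A",
                   sex = c("M", "F"))
  ds <- assemble_dataset(list(cfg1, cfg2), md, toy$pairing)
  expect_equal(sum(ds$missing_report$n_missing), 0L)
  expect_equal(n_specimens(ds), 2L)

  # label order is canonicalised from the template, not trusted from file
  shuffled <- landmark_config(toy$coords[c(3, 1, 5, 2, 4), ], specimen_id = "s2")
  ds2 <- assemble_dataset(list(cfg1, shuffled), md, toy$pairing)
  expect_equal(ds2$configurations[["s2"]]$coords, cfg1$coords)

  # extra label is an error naming the label
  bad <- landmark_config(rbind(toy$coords[-1, ], XX = c(9, 9, 9)), specimen_id = "s2")
  expect_error(assemble_dataset(list(cfg1, bad), md, toy$pairing), "XX")
  # absent metadata is an error listing the id
  expect_error(assemble_dataset(list(cfg1, cfg2), md[1, , drop = FALSE], toy$pairing),
               "s2")
})

test_that("a masked-coordinate budget of 14 is reported as 14", {
  sim <- simulate_landmarks(landmark_sim_params(
    k_pairs = 10, k_midline = 4,
    groups = list(list(name = "A", n = 10, effect = 0)),
    missing_rate = 0, seed = 11))
  ds <- sim$dataset
  set.seed(42)
  # mask exactly 14 coordinates across specimens 2..10 (keep one complete)
  slots <- cbind(specimen = sample(2:10, 14, replace = TRUE),
                 lm = sample(24, 14, replace = TRUE))
  slots <- unique(slots)
  while (nrow(slots) < 14) {
    slots <- unique(rbind(slots, c(sample(2:10, 1), sample(24, 1))))
  }
  cfgs <- ds$configurations
  for (r in seq_len(14)) {
    cf <- cfgs[[slots[r, 1]]]
    cf$missing[slots[r, 2]] <- TRUE
    cf$coords[slots[r, 2], ] <- NA_real_
    cfgs[[slots[r, 1]]] <- cf
  }
  ds2 <- assemble_dataset(cfgs, ds$metadata, ds$pairing, template = ds$labels)
  expect_equal(sum(ds2$missing_report$n_missing), 14L)
})

test_that("trait tables parse, flag incomplete rows, and hit the study sizes", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(specimen_id = c("a", "b", "c"), species = "sp1",
                   region = "northern", island = "is1", sex = c("M", "F", "M"),
                   SVL = c(60, 55, 70), ED = 3.5, EED = 5, FTL = 7, HH = c(6, NA, 6.5),
                   HL = 16, HW = 11, IND = 2.5, IOD = 6, SED = 6.5, Weight = 10)
  write.csv(df, path, row.names = FALSE)
  tab <- read_trait_table(path)
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$complete, c(TRUE, FALSE, TRUE))

  df$SVL[1] <- "sixty"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_trait_table(path), "SVL")

  sim <- simulate_traits(trait_sim_params(seed = 5))
  out <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$table[, setdiff(names(sim$table), "complete")], out, row.names = FALSE)
  tab2 <- read_trait_table(out)
  expect_equal(nrow(tab2), 567L)
  expect_equal(as.vector(table(tab2$species)[c("A", "B", "C")]), c(246L, 206L, 115L))
})
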