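test_that("write then read round-trips values, ids and labels", {
  ds <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    label = c("a", "a", "b"),
    gA = c(0, 1.5, 2.25), gB = c(3, 0, 1), gC = c(10, 20, 30),
    gD = c(0.125, 7, 2))
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_expression_table(ds, path)
    back <- read_expression_table(path)
    expect_equal(back$sample_id, ds$sample_id)
    expect_equal(back$label, ds$label)
    expect_equal(expr_matrix(back), expr_matrix(ds))
  }
})

test_that("genes-in-rows orientation and sidecar labels normalise", {
  ds <- small_planted(seed = 3, n = 4, d = 6, n_inf = 1)$data
  tdir <- withr::local_tempdir()
  tab <- file.path(tdir, "expr.tsv")
  lab <- file.path(tdir, "labels.tsv")
  write_expression_table(dplyr::select(ds, -"label"), tab,
                         orientation = "genes_in_rows")
  readr::write_tsv(dplyr::select(ds, "sample_id", "label"), lab)
  back <- read_expression_table(tab, orientation = "genes_in_rows",
                                labels_path = lab)
  expect_equal(back$sample_id, ds$sample_id)
  expect_equal(back$label, ds$label)
  expect_equal(expr_matrix(back), expr_matrix(ds))
})

test_that("negative values and duplicate ids raise typed parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,g1,g2", "s1,a,1.0,-1.0", "s2,b,2.0,3.0"),
             path)
  expect_error(read_expression_table(path), "non-negative")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,g1,g2", "s1,a,1,2", "s1,b,2,3"), path2)
  expect_error(read_expression_table(path2), "duplicate sample_id")
})

test_that("manifest-driven load recombines subtypes with their labels", {
  tdir <- withr::local_tempdir()
  sizes <- c(squamous = 840, adeno = 345)
  for (nm in names(sizes)) {
    gen <- generate_dataset(n_per_class = sizes[[nm]], d = 12,
                            n_informative = 1, seed = match(nm, names(sizes)),
                            class_names = nm)
    ds <- gen$data
    ds$sample_id <- paste0(nm, "_", ds$sample_id)
    write_expression_table(dplyr::select(ds, -"label"),
                           file.path(tdir, paste0(nm, ".csv")))
  }
  yaml::write_yaml(list(entries = list(
    list(name = "lung", subtype = "squamous", path = "squamous.csv"),
    list(name = "lung", subtype = "adeno", path = "adeno.csv"))),
    file.path(tdir, "manifest.yaml"))
  ds <- load_manifest(file.path(tdir, "manifest.yaml"), name = "lung")
  expect_equal(nrow(ds), 1185)
  expect_equal(as.vector(table(ds$label)[c("squamous", "adeno")]),
               c(840, 345))
})

test_that("stratified split honours global and per-class proportions", {
  # 175 samples at fraction 139/175 -> 139 train / 36 validation
  gen <- generate_dataset(n_per_class = c(100, 75), d = 8,
                          n_informative = 1, seed = 5)
  sp <- stratified_split(gen$data, 139 / 175, seed = 2)
  expect_equal(nrow(sp$train), 139)
  expect_equal(nrow(sp$validation), 36)

  # 50/50 two classes at 0.5 -> 25 of each class per part
  gen2 <- generate_dataset(n_per_class = c(50, 50), d = 8,
                           n_informative = 1, seed = 6)
  sp2 <- stratified_split(gen2$data, 0.5, seed = 1)
  expect_equal(as.vector(table(sp2$train$label)), c(25, 25))
  expect_equal(as.vector(table(sp2$validation$label)), c(25, 25))

  # 3 classes 500/300/200 at 0.8: per-class train counts within 1 of
  # 400/240/160, and the split partitions the samples, for 20 seeds
  gen3 <- generate_dataset(n_per_class = c(500, 300, 200), d = 5,
                           n_informative = 1, seed = 7)
  for (s in 1:20) {
    sp3 <- stratified_split(gen3$data, 0.8, seed = s)
    counts <- table(factor(sp3$train$label,
                           levels = c("class1", "class2", "class3")))
    expect_true(all(abs(as.vector(counts) - c(400, 240, 160)) <= 1))
    expect_setequal(c(sp3$train$sample_id, sp3$validation$sample_id),
                    gen3$data$sample_id)
    expect_length(intersect(sp3$train$sample_id,
                            sp3$validation$sample_id), 0)
  }
  # determinism
  a <- stratified_split(gen3$data, 0.8, seed = 11)
  b <- stratified_split(gen3$data, 0.8, seed = 11)
  expect_identical(a$train$sample_id, b$train$sample_id)
})

test_that("singleton classes are rejected by name", {
  ds <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       label = c("a", "a", "rare"),
                       g1 = c(1, 2, 3), g2 = c(4, 5, 6))
  expect_error(stratified_split(ds, 0.5), "rare")
})
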