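# Small fixture builders, all generated in code at test time.

toy_classification <- function(seed = 1) {
  generate_classification(
    n_samples = c(training = 30, `filtration:F1` = 20, validation = 20),
    n_features = 10, planted = 1:2, effect = 2, seed = seed)
}

toy_survival <- function(seed = 1) {
  generate_survival(
    n_samples = c(training = 60, `filtration:F1` = 40, validation = 40),
    n_features = 10, planted = 1:2, beta = 1, censoring_rate = 0.2,
    seed = seed)
}

write_toy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- matrix(c(1.5, 2, 3,
                4, 5.25, 6,
                7, 8, 9.125,
                10, 11, 12), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC")))
  ann <- data.frame(Sample = paste0("s", 1:4),
                    Class = c(0L, 1L, 0L, 1L),
                    Dataset = c("TR", "TR", "FL", "VAL"),
                    check.names = FALSE)
  ann[["Dataset type"]] <- c("training", "training", "filtration",
                             "validation")
  mp <- file.path(dir, "matrix.csv")
  ap <- file.path(dir, "annotation.csv")
  utils::write.csv(data.frame(Sample = rownames(m), m,
                              check.names = FALSE),
                   mp, row.names = FALSE, quote = FALSE)
  utils::write.csv(ann, ap, row.names = FALSE, quote = FALSE)
  list(matrix = mp, annotation = ap, values = m)
}
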