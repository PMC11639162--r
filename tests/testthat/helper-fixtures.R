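# Small in-code fixtures shared across test files.

toy_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                       extra_metadata_sample = FALSE,
                       bad_event = FALSE) {
  counts <- data.frame(
    sample_id = paste0("S", 1:5),
    TaxA = c(10L, 0L, 5L, 8L, 2L),
    TaxB = c(3L, 7L, 1L, 0L, 9L),
    TaxC = c(1L, 2L, 3L, 4L, 5L))
  ids <- paste0("S", 1:5)
  if (extra_metadata_sample) ids <- c(ids, "S6")
  md <- data.frame(
    sample_id = ids,
    time = seq(2, by = 2, length.out = length(ids)),
    status = rep_len(c(1, 0, 1, 1, 0), length(ids)),
    age = seq(40, by = 1, length.out = length(ids)))
  if (bad_event) md$status[2] <- 2
  cp <- file.path(dir, "counts.tsv")
  mp <- file.path(dir, "meta.tsv")
  write.table(counts, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(md, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = cp, metadata = mp)
}

random_composition <- function(n, K) {
  m <- matrix(rgamma(n * K, shape = 1), n, K)
  composition(m / rowSums(m))
}
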