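# internal helpers shared across modules

# evaluate code under a temporary RNG state; restores .Random.seed on exit
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive per-stage seeds from one master seed; keeps values inside 32-bit range
derive_seed <- function(seed, stage) {
  offsets <- c(timecourse = 101L, genome = 211L, paralogue = 307L,
               anatomy = 401L, null_pairs = 503L, pipeline = 601L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# matrix -> TSV with row-label first column; inverse of read_matrix_tsv
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv_file(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv_file(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard deviation per row/vector with a relative floor: TPM is a
# ratio of floating sums, so exactly-constant profiles can carry jitter
# of order 1e-11 that must not count as variance
row_sds <- function(mat) {
  s <- apply(mat, 1, stats::sd)
  m <- rowMeans(abs(mat))
  ifelse(s <= 1e-9 * (m + 1), 0, s)
}
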