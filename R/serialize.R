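#' Write / read a memory state
#'
#' Plain-text container for a [rekam()] memory: a one-line JSON header
#' (kernel spec, scales, labels, activation, box) followed by the
#' attractor matrix and the Gram matrix as tab-delimited numeric
#' blocks.  Reading reconstructs the memory through [rekam()] — the
#' Gram matrix is recomputed from the attractors and compared against
#' the stored block as an integrity check.
#'
#' @param M a [rekam()] memory.
#' @param path file path.
#' @export
write_memory <- function(M, path) {
  stopifnot(inherits(M, "rekam"))
  header <- jsonlite::toJSON(list(
    format = "rekam-memory", version = 1L,
    kernel = jsonlite::fromJSON(kernel_to_json(M$kernel)),
    scales = M$scales, labels = M$labels, list_tags = M$list_tags,
    activation = M$activation, box = M$box, scale_mode = M$scale_mode,
    n = M$n, m = M$m), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#REKAM-MEMORY v1", as.character(header),
               sprintf("#ATTRACTORS %d %d", M$n, M$m)), con)
  utils::write.table(format(M$attractors, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("#GRAM %d %d", M$m, M$m), con)
  utils::write.table(format(M$gram, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_memory
#' @return `read_memory()`: the reconstructed [rekam()] memory.
#' @export
read_memory <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "#REKAM-MEMORY v1") stop("not a rekam memory file")
  hd <- jsonlite::fromJSON(lines[2L])
  stopifnot(startsWith(lines[3L], "#ATTRACTORS"))
  n <- hd$n; m <- hd$m
  att_lines <- lines[4:(3 + n)]
  X <- do.call(rbind, lapply(strsplit(att_lines, "\t"), as.numeric))
  stopifnot(startsWith(lines[4L + n], "#GRAM"))
  gram_lines <- lines[(5L + n):(4L + n + m)]
  G <- do.call(rbind, lapply(strsplit(gram_lines, "\t"), as.numeric))
  ks <- kernel_spec(family = hd$kernel$family,
                    sigma_v = if (is.null(hd$kernel$sigma_v)) 1 else hd$kernel$sigma_v,
                    sigma_r = if (is.null(hd$kernel$sigma_r)) 0.25 else hd$kernel$sigma_r,
                    weights = hd$kernel$weights,
                    bias = if (is.null(hd$kernel$bias)) 0 else hd$kernel$bias)
  M <- rekam(X, kernel = ks, scales = hd$scales,
             labels = hd$labels, list_tags = hd$list_tags,
             activation = hd$activation, box = hd$box,
             scale_mode = hd$scale_mode)
  if (max(abs(M$gram - G)) > 1e-6)
    warning("stored Gram block disagrees with the recomputed Gram matrix")
  M
}
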