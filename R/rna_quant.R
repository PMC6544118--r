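#' Reads per kilobase of CDS per million mapped reads (rpkM)
#'
#' `rpkM = count / ((cds_length_nt / 1000) * (total_mapped / 1e6))`, with the
#' quantifiability rule that a gene needs at least `min_reads` (default 10)
#' mapped reads. `total_mapped` is the number of reads mapped to coding
#' sequence.
#'
#' @param read_count Non-negative integer vector.
#' @param cds_length_nt Positive CDS lengths in nucleotides.
#' @param total_mapped Positive library size (reads mapped to CDS).
#' @param min_reads Quantifiability threshold, default 10.
#' @return data.frame: read_count, cds_length_nt, rpkM, quantifiable.
#' @examples
#' rpkm(10, 1000, 1e6)  # rpkM 10, quantifiable
#' @export
rpkm <- function(read_count, cds_length_nt, total_mapped, min_reads = 10L) {
  if (any(cds_length_nt <= 0)) .stopf("cds_length_nt must be positive")
  if (length(total_mapped) != 1L || total_mapped <= 0)
    .stopf("total_mapped must be a positive scalar")
  if (any(read_count < 0)) .stopf("read counts must be non-negative")
  data.frame(read_count = read_count, cds_length_nt = cds_length_nt,
             rpkM = read_count / ((cds_length_nt / 1000) *
                                    (total_mapped / 1e6)),
             quantifiable = read_count >= min_reads)
}

#' rpkM quantification of a counts table
#'
#' @param counts data.frame with columns gene_id, read_count, cds_length_nt.
#' @param total_mapped Library size; default the sum of `read_count`
#'   (all reads mapped to CDS).
#' @param min_reads See [rpkm()].
#' @return data.frame: gene_id, read_count, cds_length_nt, rpkM,
#'   quantifiable.
#' @export
rna_quant_table <- function(counts, total_mapped = sum(counts$read_count),
                            min_reads = 10L) {
  stopifnot(all(c("gene_id", "read_count", "cds_length_nt") %in% names(counts)))
  out <- rpkm(counts$read_count, counts$cds_length_nt, total_mapped,
              min_reads)
  cbind(gene_id = counts$gene_id, out, stringsAsFactors = FALSE)
}
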