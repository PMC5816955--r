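#' Convert Ct values to arbitrary expression units
#'
#' `E = 2500 * 1.93^(ct_reference - ct_gene)`: the assay's fixed
#' arbitrary-unit formula, with the target gene normalized to the
#' Rps11 reference. Strictly increasing in the reference Ct and
#' strictly decreasing in the gene Ct; equal Ct values give E = 2500.
#'
#' @param ct_reference Reference-gene Ct (cycles), finite.
#' @param ct_gene Target-gene Ct (cycles), finite.
#' @return Expression in arbitrary units (vectorized).
#' @export
#' @examples
#' ct_to_units(22, 22)        # 2500
#' ct_to_units(22, 21)        # one cycle earlier: 2500 * 1.93
ct_to_units <- function(ct_reference, ct_gene) {
  if (any(!is.finite(ct_reference)) || any(!is.finite(ct_gene)))
    stop("Ct values must be finite", call. = FALSE)
  2500 * 1.93^(ct_reference - ct_gene)
}

#' Summarize technical qPCR replicates into per-sample expression
#'
#' Technical replicate Ct values are averaged on the Ct scale
#' (arithmetic mean) per sample and gene before the unit transform; E is
#' then computed from the mean gene Ct against the mean reference Ct of
#' the same sample. Genes whose mean Ct sits at the 40-cycle assay cap
#' are flagged below detection; samples missing the reference gene are
#' flagged and get no E.
#'
#' @param records data.frame with columns `sample`, `gene`, `ct` (one
#'   row per technical replicate), e.g. from [simulate_qpcr_ct()].
#' @param reference Reference gene name (default "Rps11").
#' @param ct_cap Assay cycle cap (default 40).
#' @return data.frame: `sample`, `gene`, `n_replicates`, `mean_ct`,
#'   `expression` (arbitrary units), `below_detection`, `flagged`.
#' @export
summarize_replicates <- function(records, reference = "Rps11",
                                 ct_cap = 40) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(records)))
    stop("records must have columns sample, gene, ct", call. = FALSE)
  if (any(records$ct <= 0 | records$ct > ct_cap))
    stop("Ct values must lie in (0, ", ct_cap, "]", call. = FALSE)
  agg <- aggregate(ct ~ sample + gene, data = records, FUN = mean)
  nrep <- aggregate(ct ~ sample + gene, data = records, FUN = length)
  agg$n_replicates <- nrep$ct
  ref <- agg[agg$gene == reference, c("sample", "ct")]
  names(ref)[2] <- "ref_ct"
  out <- merge(agg[agg$gene != reference, ], ref,
               by = "sample", all.x = TRUE)
  out$flagged <- is.na(out$ref_ct)
  if (any(out$flagged))
    warning("sample(s) missing the reference gene: ",
            paste(unique(out$sample[out$flagged]), collapse = ", "))
  out$expression <- NA_real_
  ok <- !out$flagged
  out$expression[ok] <- ct_to_units(out$ref_ct[ok], out$ct[ok])
  out$below_detection <- !out$flagged & out$ct >= ct_cap - 1e-9
  data.frame(sample = out$sample, gene = out$gene,
             n_replicates = out$n_replicates, mean_ct = out$ct,
             reference_ct = out$ref_ct, expression = out$expression,
             below_detection = out$below_detection,
             flagged = out$flagged, stringsAsFactors = FALSE)
}
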