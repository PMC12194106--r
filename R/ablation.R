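#' Ablation variant grid
#'
#' The component-substitution grid used for ablation studies: each row
#' names an encoder variant (plain double-conv baseline, Inception,
#' dilated Inception, or full RDI), a bottleneck variant (none, ASPP,
#' TSA-only, GSA-only, or the dual Transformer attention), and a skip
#' variant (plain concatenation or cross-attention). Row 1 is the plain
#' U-Net-shaped baseline; the last row is the full model.
#'
#' @return A data frame with columns `encoder`, `bottleneck`, `skip`.
#' @export
ablation_grid <- function() {
  data.frame(
    encoder = c("plain_conv", "RDI", "inception", "plain_conv", "RDI",
                "plain_conv", "RDI", "RDI", "RDI", "dilated_inception", "RDI"),
    bottleneck = c("none", "none", "ASPP", "ASPP", "DTA",
                   "DTA", "ASPP", "GSA_only", "TSA_only", "DTA", "DTA"),
    skip = c("plain_skip", "CASC", "plain_skip", "CASC", "plain_skip",
             "CASC", "CASC", "CASC", "CASC", "CASC", "CASC"),
    stringsAsFactors = FALSE
  )
}
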