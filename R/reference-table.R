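#' Packaged reference weight table
#'
#' The published indicator weight table shipped with the package: the
#' expert-elicited AHP column plus, per epoch (2000/2010/2020), the entropy
#' (EEM) column and the combined column, all printed at 4 decimal places.
#' The AHP judgment matrices behind the subjective column were never
#' published, so the printed AHP weights are the canonical subjective input;
#' the combined column is what [combine_weights()] should reproduce from the
#' other two.
#'
#' @return list with `ahp` (a [weight_set()]) and, per epoch, `eem` and
#'   `combined` weight sets, plus the raw `table` data.frame.
#' @export
reference_weight_table <- function() {
  path <- system.file("extdata", "table2_weights.csv", package = "recpot",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list(
    ahp = weight_set(stats::setNames(df$w_ahp, df$code), kind = "ahp"),
    table = df)
  for (ep in c("2000", "2010", "2020")) {
    out[[ep]] <- list(
      eem = weight_set(stats::setNames(df[[paste0("eem_", ep)]], df$code),
                       kind = "eem", epoch = ep, normalize = TRUE),
      combined = weight_set(stats::setNames(df[[paste0("wi_", ep)]],
                                            df$code),
                            kind = "combined", epoch = ep, normalize = TRUE))
  }
  out
}
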