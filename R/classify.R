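# Rule-based neuron class assignment from connectivity and ROI synapse
# counts. All thresholds are inclusive (>=).

#' Third-order olfactory neuron (TOON) call
#'
#' A neuron is a TOON when it receives at least `frac_single` (1%) of its
#' synaptic input — or else at least `conn_single` (10) connections —
#' from a single olfactory projection neuron, or otherwise at least
#' `frac_sum` (10%) of its input — or else `conn_sum` (100) connections —
#' from olfactory projection neurons combined. Input counts are expected
#' to already exclude any named excluded region (e.g. the mushroom-body
#' calyx). A neuron with zero total input is not a TOON.
#'
#' @param alpn_inputs numeric vector: input synapse counts from each
#'   olfactory projection neuron (one entry per source neuron).
#' @param total_input total input synapse count of the neuron.
#' @param frac_single,conn_single single-source thresholds.
#' @param frac_sum,conn_sum combined-source thresholds.
#' @return Logical scalar.
#' @export
classify_toon <- function(alpn_inputs, total_input,
                          frac_single = 0.01, conn_single = 10,
                          frac_sum = 0.10, conn_sum = 100) {
  if (total_input < 0 || any(alpn_inputs < 0)) stopf("counts must be >= 0")
  if (total_input == 0) return(FALSE)
  if (length(alpn_inputs) == 0) return(FALSE)
  best <- max(alpn_inputs)
  total_alpn <- sum(alpn_inputs)
  (best / total_input >= frac_single || best >= conn_single) ||
    (total_alpn / total_input >= frac_sum || total_alpn >= conn_sum)
}

#' Lateral horn neuron (LHN) call
#'
#' LHNs are the subset of TOONs with at least `threshold` (10) pre- or
#' postsynapses inside the lateral horn volume.
#'
#' @param is_toon logical: the neuron passed [classify_toon()].
#' @param lh_synapses pre- plus postsynapse count inside the LH.
#' @param threshold inclusive synapse threshold (default 10).
#' @return Logical (vectorised).
#' @export
classify_lhn <- function(is_toon, lh_synapses, threshold = 10) {
  is_toon & lh_synapses >= threshold
}

#' Load and validate a hemilineage-to-transmitter evidence table
#'
#' @param evidence data frame with columns `hemilineage`, `transmitter`;
#'   conflicting rows (one hemilineage, two transmitters) are rejected.
#' @return Named character vector hemilineage -> transmitter.
#' @export
load_transmitter_evidence <- function(evidence) {
  stopifnot(all(c("hemilineage", "transmitter") %in% names(evidence)))
  tab <- unique(evidence[, c("hemilineage", "transmitter")])
  dup <- tab$hemilineage[duplicated(tab$hemilineage)]
  if (length(dup) > 0)
    stopf("conflicting transmitter evidence for hemilineage(s): %s",
          paste(unique(dup), collapse = ", "))
  stats::setNames(tab$transmitter, tab$hemilineage)
}

#' Putative transmitter by hemilineage
#'
#' Neurons sharing a hemilineage are assumed to share their fast-acting
#' transmitter: each neuron's transmitter is looked up from the evidence
#' table by its hemilineage; hemilineages without evidence yield
#' `"unknown"`.
#'
#' @param hemilineage character vector of hemilineage labels.
#' @param evidence evidence table (data frame) or the named vector
#'   returned by [load_transmitter_evidence()].
#' @return Character vector of transmitters.
#' @export
transmitter_by_hemilineage <- function(hemilineage, evidence) {
  lut <- if (is.data.frame(evidence)) load_transmitter_evidence(evidence)
  else evidence
  out <- lut[hemilineage]
  out[is.na(out)] <- "unknown"
  unname(out)
}
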