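# Integration of diurnal transcript amplitudes and measured fluxomes with
# model-predicted flux changes.

#' Flag diurnally expressed genes
#'
#' A gene is diurnal when its log2 expression amplitude over the cycle
#' exceeds the cutoff and it shows an unambiguous phase (an increase during
#' one period and the opposite change during the other).
#'
#' @param profiles data.frame with columns gene_id, log2_amplitude, phase
#'   (`"light_up"`, `"dark_up"` or `"none"`).
#' @param cutoff amplitude threshold (default 0.8).
#' @return the profiles with a logical `diurnal` column.
#' @export
classify_diurnal <- function(profiles, cutoff = 0.8) {
  stopifnot(all(c("gene_id", "log2_amplitude") %in% names(profiles)))
  if (is.null(profiles$phase)) profiles$phase <- "none"
  profiles$diurnal <- profiles$log2_amplitude > cutoff &
    profiles$phase != "none"
  profiles
}

#' Map transcript profiles onto reactions via gene associations
#'
#' @param network a `MetabolicNetwork`.
#' @param profiles transcript profile data.frame (gene_id, ...).
#' @return named list: reaction id -> data.frame of matching profiles
#'   (zero-row for reactions without genes); many-to-many preserved.
#' @export
map_genes_to_reactions <- function(network, profiles) {
  out <- lapply(network$reactions, function(r) {
    profiles[profiles$gene_id %in% r$genes, , drop = FALSE]
  })
  names(out) <- reaction_ids(network)
  out
}

#' Flux-transcript concordance records
#'
#' Crosses the model's light-vs-dark flux verdicts with transcript
#' diurnality. A reaction's flux is diurnal when its comparison verdict is
#' reversed/increased/decreased; its transcript side is diurnal when any
#' mapped gene is diurnal. Directions agree when the flux change direction
#' matches the transcript phase (flux higher in the light with light_up
#' genes, or lower with dark_up genes); reactions with no diurnal gene or no
#' flux change get NA.
#'
#' @param comparison data.frame from [compare_conditions()] with condition A
#'   = light, condition B = dark.
#' @param mapped output of [map_genes_to_reactions()] on diurnal-classified
#'   profiles.
#' @return data.frame of ConcordanceRecords: reaction, genes, n_diurnal_genes,
#'   transcript_diurnal, flux_diurnal, directions_agree, class.
#' @export
concordance <- function(comparison, mapped) {
  out <- do.call(rbind, lapply(seq_len(nrow(comparison)), function(i) {
    rid <- comparison$reaction[i]
    prof <- mapped[[rid]]
    if (is.null(prof)) prof <- data.frame()
    tr_d <- nrow(prof) > 0 && any(prof$diurnal)
    fx_d <- comparison$verdict[i] %in% c("reversed", "increased", "decreased")
    agree <- NA
    if (tr_d && fx_d) {
      phases <- prof$phase[prof$diurnal]
      # flux "light-up" when increased in condition A (light) or reversed
      # towards positive light flux
      flux_dir <- switch(comparison$verdict[i],
                         increased = "light_up",
                         decreased = "dark_up",
                         reversed = if (comparison$mean_a[i] > 0) "light_up" else "dark_up")
      agree <- any(phases == flux_dir)
    }
    cls <- if (tr_d && fx_d) "both" else if (fx_d) "flux_only"
      else if (tr_d) "transcript_only" else "neither"
    data.frame(reaction = rid,
               genes = paste(unique(prof$gene_id), collapse = ";"),
               n_diurnal_genes = if (nrow(prof)) sum(prof$diurnal) else 0L,
               transcript_diurnal = tr_d, flux_diurnal = fx_d,
               directions_agree = agree, class = cls,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overlay a measured fluxome on a predicted optimal flux vector
#'
#' Pairs in vivo and in silico fluxes on their shared reaction index
#' (normalized to 6 C-mol substrate), reporting rank correlation and
#' relative deviations.
#'
#' @param measured named numeric vector of measured fluxes
#'   (C-mol per 6 C-mol substrate).
#' @param predicted named numeric vector of predicted fluxes in C-mol on any
#'   substrate basis; rescaled to the 6 C-mol basis via `predicted_cmol`.
#' @param predicted_cmol substrate C-mol of the predicted vector's basis
#'   (e.g. 100 for the CO2 normalization); default 6 (already on basis).
#' @return list(pairs = data.frame(reaction, measured, predicted,
#'   rel_deviation), correlation = Spearman rank correlation, n_unmatched).
#' @export
fluxome_overlay <- function(measured, predicted, predicted_cmol = 6) {
  common <- intersect(names(measured), names(predicted))
  if (!length(common)) stop("fluxome_overlay: no shared reactions")
  pred <- predicted[common] * 6 / predicted_cmol
  meas <- measured[common]
  rel <- ifelse(abs(meas) > 1e-12, (pred - meas) / abs(meas), NA_real_)
  corr <- if (length(common) > 2)
    suppressWarnings(stats::cor(meas, pred, method = "spearman")) else NA_real_
  list(pairs = data.frame(reaction = common, measured = as.numeric(meas),
                          predicted = as.numeric(pred),
                          rel_deviation = as.numeric(rel),
                          stringsAsFactors = FALSE),
       correlation = corr,
       n_unmatched = length(union(names(measured), names(predicted))) -
         length(common))
}
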