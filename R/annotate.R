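# Missense versus gene-damaging classification of somatic alterations.

DAMAGING_EFFECTS <- c("nonsense", "splice", "frameshift", "inframe_large",
                      "structural")

#' Classify alteration effects as missense versus gene damaging
#'
#' Missense mutations create a full-length protein (`point_missense`);
#' nonsense (early stop), splice-site, frameshift, larger in-frame indels
#' and structural alterations probably damage the gene product
#' (`gene_damaging`). Effects outside the declared vocabulary — including
#' synonymous changes — are returned as `unclassified`, never silently
#' grouped. Deterministic and total; no alteration lands in both groups.
#'
#' @param effect character vector of consequence classes (`missense`,
#'   `nonsense`, `splice`, `frameshift`, `inframe_large`, `structural`).
#' @param inframe_damaging whether in-frame indels of three or more codons
#'   (`inframe_large`) count as gene damaging (default TRUE).
#' @return Character vector: `point_missense`, `gene_damaging` or
#'   `unclassified`.
#' @export
classify_damage <- function(effect, inframe_damaging = TRUE) {
  dmg <- DAMAGING_EFFECTS
  if (!inframe_damaging) dmg <- setdiff(dmg, "inframe_large")
  out <- rep("unclassified", length(effect))
  out[effect == "missense"] <- "point_missense"
  out[effect %in% dmg] <- "gene_damaging"
  if (!inframe_damaging) out[effect == "inframe_large"] <- "unclassified"
  out
}

#' Per-gene damage-call table
#'
#' @param mutations table with `gene` and `effect` columns (one row per
#'   alteration).
#' @param inframe_damaging see [classify_damage()].
#' @return data.frame `gene`, `effect`, `damage_call`.
#' @export
damage_table <- function(mutations, inframe_damaging = TRUE) {
  data.frame(
    gene = mutations$gene, effect = mutations$effect,
    damage_call = classify_damage(mutations$effect, inframe_damaging),
    stringsAsFactors = FALSE
  )
}
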