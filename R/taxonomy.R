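# The fixed behavior taxonomy: eight fine-scale behaviors, two principal
# behaviors, and the parent mapping between them.

FINESCALE_TO_PRINCIPAL <- c(
  Feeding       = "Interested",
  Biting        = "Interested",
  Nibble        = "Interested",
  Exploring     = "Interested",
  Passing       = "Uninterested",
  Startle       = "Uninterested",
  BurstSwimming = "Uninterested",
  Fleeing       = "Uninterested"
)

#' The eight fine-scale behavior classes
#' @return Character vector of the eight fine-scale behavior names.
#' @export
finescale_behaviors <- function() names(FINESCALE_TO_PRINCIPAL)

#' The two principal behavior classes
#' @return `c("Interested", "Uninterested")`.
#' @export
principal_behaviors <- function() c("Interested", "Uninterested")

#' Map fine-scale behaviors to their principal parent
#'
#' Feeding, Biting, Nibble and Exploring are Interested; Passing, Startle,
#' Burst swimming and Fleeing are Uninterested. The mapping is fixed.
#'
#' @param fine Character vector of fine-scale behavior labels.
#' @return Character vector of principal labels (`Interested`/`Uninterested`).
#' @export
map_finescale_to_parent <- function(fine) {
  fine <- as.character(fine)
  unknown <- setdiff(unique(fine[!is.na(fine)]), names(FINESCALE_TO_PRINCIPAL))
  if (length(unknown) > 0) {
    stopf("unknown fine-scale behavior label(s): %s",
          paste(unknown, collapse = ", "))
  }
  unname(FINESCALE_TO_PRINCIPAL[fine])
}
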