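# Scoring a pipeline run against synthetic ground truth.

#' Score cell-to-ommatidium assignment against ground truth
#'
#' Each detected ommatidium anchor is matched to the nearest true ommatidium
#' centre. A true nucleus counts as correctly assigned when the assigned cell
#' blob that contains its centre pixel (or, failing that, whose centroid lies
#' within one nucleus radius of it) belongs to the anchor matched to its true
#' parent ommatidium. Undetected or unassigned nuclei count as incorrect.
#'
#' @param result a `ccrit_result` from [run_ccrit()], or a `cell_map`
#' @param truth the `ccrit_truth` the specimen was rendered from
#' @return a list with `accuracy` (fraction of true nuclei correctly
#'   assigned), `n_correct`, `n_nuclei`, and the per-nucleus `detail` tibble
#' @export
score_assignment <- function(result, truth) {
  cm <- if (inherits(result, "ccrit_result")) result$cell_map else result
  frame <- truth$params$frame
  # label image of assigned cells
  cell_img <- matrix(0L, frame, frame)
  for (i in seq_len(nrow(cm))) {
    cell_img[cm$pixels[[i]]] <- i
  }
  # anchor -> true ommatidium by nearest centre
  anchors <- unique(cm[, c("ommatidium_label", "anchor_row", "anchor_col")])
  anchor_omm <- vapply(seq_len(nrow(anchors)), function(a) {
    d2 <- (truth$ommatidia$center_row - anchors$anchor_row[a])^2 +
      (truth$ommatidia$center_col - anchors$anchor_col[a])^2
    truth$ommatidia$ommatidium[which.min(d2)]
  }, integer(1))
  names(anchor_omm) <- anchors$ommatidium_label

  nuc <- truth$nuclei
  assigned_omm <- vapply(seq_len(nrow(nuc)), function(i) {
    r <- round(nuc$center_row[i]); c <- round(nuc$center_col[i])
    j <- if (r >= 1 && r <= frame && c >= 1 && c <= frame) cell_img[r, c] else 0L
    if (j == 0L) {
      d2 <- (cm$centroid_row - nuc$center_row[i])^2 +
        (cm$centroid_col - nuc$center_col[i])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > nuc$radius[i]) return(NA_integer_)
    }
    anchor_omm[[cm$ommatidium_label[j]]]
  }, integer(1))

  detail <- tibble::tibble(
    ommatidium = nuc$ommatidium,
    cell_index = nuc$cell_index,
    assigned_ommatidium = assigned_omm,
    correct = !is.na(assigned_omm) & assigned_omm == nuc$ommatidium
  )
  list(
    accuracy = mean(detail$correct),
    n_correct = sum(detail$correct),
    n_nuclei = nrow(detail),
    detail = detail
  )
}
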