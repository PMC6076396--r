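#' Segmentation quality benchmark on synthetic fixtures
#'
#' Renders a fixed fixture set from the well-separated easy panel (by default
#' 4 accessions x 2 plants x days 8, 11, 14, 17, 20 at a 128 px canvas), runs
#' [segment_plant()] on every frame and scores it against the generator's
#' ground-truth mask.
#'
#' @param seed master seed for the fixture plants.
#' @param days days sampled per plant.
#' @param n_plants plants per accession.
#' @param canvas_size canvas side in pixels.
#' @return list with `results` (tibble: accession, plant, day, truth/pred
#'   areas, `iou`) and `mean_iou`.
#' @export
segmentation_benchmark <- function(seed = 1, days = c(8, 11, 14, 17, 20),
                                   n_plants = 2, canvas_size = 128) {
  panel <- easy_accession_panel()
  plant_seeds <- with_local_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, length(panel) * n_plants),
           length(panel), n_plants))
  rows <- list()
  for (ci in seq_along(panel)) {
    for (p in seq_len(n_plants)) {
      for (d in days) {
        r <- render_frame(panel[[ci]], day = d, canvas_size = canvas_size,
                          seed = plant_seeds[ci, p])
        m <- segment_plant(r$frame)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          accession = panel[[ci]]$name, plant = p, day = d,
          truth_area = sum(r$mask), pred_area = sum(m),
          iou = mask_iou(m, r$mask))
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  list(results = results, mean_iou = mean(results$iou))
}
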