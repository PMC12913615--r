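#' Default game catalogue of the computerized cognitive training platform
#'
#' The training software offers 18 game-based tasks spanning five cognitive
#' domains: attention (3 games), working memory (3), executive function (2),
#' visuospatial ability (6), and language/calculation (4). The synthetic
#' training-stream generator cycles tasks through this catalogue, and the
#' leave-one-game-out sensitivity analysis excludes each entry in turn.
#'
#' @return A `data.frame` with 18 rows and columns `game_id` (short stable
#'   token), `name` (display name) and `domain` (one of `attention`,
#'   `working_memory`, `executive_function`, `visuospatial_ability`,
#'   `language_calculation`).
#' @examples
#' cat18 <- default_catalog()
#' table(cat18$domain)
#' @export
default_catalog <- function() {
  data.frame(
    game_id = c(
      "circles_order", "numbers_order", "numbers_reverse",
      "circles_reverse", "grow_tomatoes", "pair_matching",
      "collect_fruit", "previous_card",
      "treasure_hunt", "spot_difference", "fishing_challenge",
      "merge_shapes", "box_sorting", "touch_card",
      "train_arrival", "receipt_total", "reverse_calc", "honeycomb"
    ),
    name = c(
      "Tap the Circles in Order", "Tap the Numbers in Order",
      "Press the Number in Reverse Order",
      "Tap the Circles in Reverse Order", "Grow the Tomatoes",
      "Pair Matching",
      "Quickly Collect the Fruit", "Remember the Previous Card",
      "Treasure Hunt", "Spot the Difference", "Fishing Challenge",
      "Merge the Shapes", "Colorful Box Sorting", "Touch-Touch Card Game",
      "When Will It Arrive?", "How Much Is It?", "Reverse Calculation",
      "Crack the Honeycomb"
    ),
    domain = rep(
      c("attention", "working_memory", "executive_function",
        "visuospatial_ability", "language_calculation"),
      times = c(3L, 3L, 2L, 6L, 4L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Cognitive domains recognised by the catalogue
#' @noRd
catalog_domains <- function() {
  c("attention", "working_memory", "executive_function",
    "visuospatial_ability", "language_calculation")
}
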