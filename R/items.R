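#' The 17-item depression rating battery
#'
#' Returns the item metadata used throughout the package: the 17
#' interviewer-rated depression symptoms, grouped into five categories
#' (2 affective, 4 cognitive, 7 arousal/somatic, 3 sleep, 1 insight).
#' Affective and cognitive items, somatic anxiety and hypochondriasis are
#' scored 0-4; all other items 0-2.
#'
#' @return A data.frame with columns `name`, `category` and `scale_max`,
#'   one row per item, in canonical order.
#' @export
#' @examples
#' battery <- hdrs_items()
#' table(battery$category)
hdrs_items <- function() {
  items <- data.frame(
    name = c("depressed_mood", "psychic_anxiety",
             "guilt", "suicidality", "work_activities", "retardation",
             "agitation", "somatic_anxiety", "general_somatic", "genital",
             "hypochondriasis", "gastrointestinal", "weight_loss",
             "insomnia_early", "insomnia_middle", "insomnia_late",
             "insight"),
    category = c("affective", "affective",
                 "cognitive", "cognitive", "cognitive", "cognitive",
                 rep("arousal_somatic", 7L),
                 rep("sleep", 3L),
                 "insight"),
    stringsAsFactors = FALSE
  )
  items$scale_max <- ifelse(
    items$category %in% c("affective", "cognitive") |
      items$name %in% c("somatic_anxiety", "hypochondriasis"), 4L, 2L)
  items
}

validate_items <- function(items) {
  stopifnot(is.data.frame(items),
            all(c("name", "category", "scale_max") %in% names(items)))
  if (anyDuplicated(items$name)) stop_("duplicated item names")
  ok <- items$category %in% c("affective", "cognitive", "arousal_somatic",
                              "sleep", "insight")
  if (!all(ok)) stop_("unknown item category: %s",
                      paste(unique(items$category[!ok]), collapse = ", "))
  if (!all(items$scale_max %in% c(2L, 4L)))
    stop_("scale_max must be 2 or 4")
  invisible(items)
}
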