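#' The 34-group food-grouping scheme
#'
#' Food items from 24-hour recalls are aggregated into 34 food groups adapted
#' from the USDA Food and Nutrient Database for Dietary Studies (FNDDS), with
#' dairy split into low-fat vs whole-fat and grain products split into good vs
#' poor fiber sources (good source: strictly more than 2.5 g fiber per
#' serving).
#'
#' @return A data frame with columns `group_id` (`"G1"`..`"G34"`) and `label`.
#' @examples
#' head(food_groups())
#' @export
food_groups <- function() {
  data.frame(
    group_id = paste0("G", 1:34),
    label = c(
      "Low fat dairy products",
      "Whole fat dairy products",
      "Red meat",
      "Poultry",
      "Organ meat",
      "Fish",
      "Meat, poultry, fish with nonmeat items",
      "Frozen and shelf-stable plate meals, soups, gravies with meat base",
      "Eggs",
      "Legumes",
      "Nuts and seeds",
      "Flour and dry mixes, yeast breads, rolls, quick bread",
      "Cakes, cookies, pies, pastries, bars",
      "Crackers and salty snacks from grain products",
      "Pancakes, waffles, French toast, other grain products",
      "Pastas, cooked cereals, rice",
      "Cereals, not cooked or non-specified as to cooked",
      "Grain mixtures, frozen plate meals, soups",
      "Meat substitutes, mainly cereal protein",
      "Cereals, grains good source of fiber",
      "Cereals, grains poor source of fiber",
      "Fruits",
      "Fruit juices",
      "Starchy vegetables",
      "Dark green vegetables",
      "Yellow and red vegetables",
      "Other vegetables",
      "Fats",
      "Oils",
      "Salad dressing",
      "Sugars and sweets",
      "Nonalcoholic beverages",
      "Alcoholic beverages",
      "Formulated nutrition beverages"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname food_groups
#' @export
food_group_ids <- function() paste0("G", 1:34)

# column names used for per-day intakes in the participant schema
day_intake_cols <- function(day) paste0(tolower(food_group_ids()), "_day", day)
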