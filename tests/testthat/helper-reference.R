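# Published per-whale migration event dates for the tagged cohort, used as
# *inputs* to the duration arithmetic (dates as printed, here in ISO form;
# NA where a tag stopped before the event).

reference_event_dates <- function() {
  tibble::tibble(
    animal_id = c("196721", "196724", "201357", "220659", "220665",
                  "220666", "235819", "235820", "235821", "235822",
                  "235823", "245465"),
    start = as.Date(c("2021-02-03", "2021-04-21", "2021-01-26",
                      "2022-01-18", "2021-07-10", "2021-06-09",
                      "2023-06-01", "2023-04-04", "2023-02-09",
                      "2022-10-06", "2023-04-05", "2023-06-17")),
    arrival = as.Date(c("2021-03-03", NA, "2021-03-03", "2022-02-18",
                        "2021-09-01", "2021-07-20", NA, "2023-05-13",
                        "2023-03-12", "2022-12-08", "2023-05-15",
                        "2023-07-22")),
    departure = as.Date(c(NA, NA, NA, NA, "2021-10-22", NA, NA,
                          "2023-08-23", NA, "2023-03-02", "2023-07-22",
                          NA)),
    return_north = as.Date(c(NA, NA, NA, NA, NA, NA, NA, "2023-09-26",
                             NA, "2023-04-04", NA, NA)))
}
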