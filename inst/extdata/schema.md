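# CSV schemas

All interchange files are plain CSV with a mandatory header row.

## trees.csv (long form: one row per tree per measurement)

| column      | type    | description                                        |
|-------------|---------|----------------------------------------------------|
| tree_id     | string  | unique tag of the tree                             |
| plot_id     | string  | plot the tree belongs to                           |
| subplot     | integer | 1..16, row-major cell of the 4 x 4 subplot grid    |
| year        | integer | measurement year (must be a schedule year)         |
| diameter_mm | numeric | diameter at 1.4 m, mm; empty when unmeasured/dead  |
| status      | string  | "alive" or "dead"                                  |

Years with no row are missing data (before the first row: not yet
tagged). Once a tree is recorded dead it may not be recorded alive
again. A `species` column is tolerated and ignored.

## plots.csv (one row per plot)

| column                | type    | description                           |
|-----------------------|---------|---------------------------------------|
| plot_id               | string  | unique plot id                        |
| transect_id           | string  | transect the plot lies on             |
| elevation_m           | numeric | metres above sea level                |
| slope_deg             | numeric | slope in degrees                      |
| landform_index        | numeric | terrain-shape index, degrees          |
| soil_avP_ug_g         | numeric | soil-available P, micrograms per gram (> 0) |
| epicentre_distance_km | numeric | distance from earthquake epicentre, km (> 0) |

## observations.csv (one row per tree x survival interval)

| column          | type    | description                                 |
|-----------------|---------|---------------------------------------------|
| tree_id         | string  | tree tag                                    |
| plot_id         | string  | plot id                                     |
| subplot         | integer | subplot of the tree (central: 6, 7, 10, 11) |
| start_year      | integer | survival interval start                     |
| end_year        | integer | survival interval end                       |
| delta_t         | numeric | end_year - start_year, years                |
| period          | integer | survival period regime: 1, 2 or 3           |
| outcome         | integer | 1 alive at end_year, 0 dead                 |
| diameter_std    | numeric | diameter - 164 mm                           |
| diameter_sq_std | numeric | (diameter - 164)^2                          |
| local_ba_std    | numeric | neighbourhood basal area - 50 m2/ha         |
| growth_prev     | numeric | previous-window growth, mm/yr               |
| growth_lag      | numeric | lagged-window growth, mm/yr                 |
| soil_p_std      | numeric | ln(soil P) - 2.7                            |
| landform_std    | numeric | landform index - 20 degrees                 |
| elevation_std   | numeric | (elevation - 1000 m) / 100 m                |
| distance_std    | numeric | ln(distance km) - 2.9                       |
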