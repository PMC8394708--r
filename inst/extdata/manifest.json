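{
  "files": {
    "cost_components.csv": "8fbb6ec05fa321aace30cb15ad06f38a",
    "outcome_summary.csv": "83dcb6d5639f3d02dd7157a85230cee7",
    "published_cost_differences.csv": "a4142b1ac5e8dbf85acf0aa9ca606af1",
    "scenario_expectations.csv": "4de5cd7339f95c5270cdb6e016b2d66c",
    "screening_costs.csv": "68327e33118c82424ea77057bfdc7435",
    "stage_tables.csv": "8b44b53dbec5711ae9679164c952ecaf"
  }
}
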