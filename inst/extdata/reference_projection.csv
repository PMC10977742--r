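scenario,indicator,year,prevalence
status_quo,overweight,2022,31.6
status_quo,overweight,2023,31.6
status_quo,overweight,2024,31.6
status_quo,overweight,2025,31.6
status_quo,overweight,2026,31.7
status_quo,overweight,2027,31.7
scenario1,overweight,2022,31.6
scenario1,overweight,2023,31.6
scenario1,overweight,2024,31.5
scenario1,overweight,2025,31.5
scenario1,overweight,2026,31.4
scenario1,overweight,2027,31.2
scenario2,overweight,2022,31.6
scenario2,overweight,2023,31.6
scenario2,overweight,2024,31.6
scenario2,overweight,2025,31.5
scenario2,overweight,2026,31.4
scenario2,overweight,2027,31.4
scenario3,overweight,2022,31.6
scenario3,overweight,2023,31.5
scenario3,overweight,2024,31.5
scenario3,overweight,2025,31.3
scenario3,overweight,2026,31.1
scenario3,overweight,2027,30.9
status_quo,obesity1,2022,11.8
status_quo,obesity1,2023,11.8
status_quo,obesity1,2024,11.9
status_quo,obesity1,2025,12.0
status_quo,obesity1,2026,12.1
status_quo,obesity1,2027,12.2
scenario1,obesity1,2022,11.8
scenario1,obesity1,2023,11.8
scenario1,obesity1,2024,11.8
scenario1,obesity1,2025,11.8
scenario1,obesity1,2026,11.8
scenario1,obesity1,2027,11.7
scenario2,obesity1,2022,11.8
scenario2,obesity1,2023,11.8
scenario2,obesity1,2024,11.8
scenario2,obesity1,2025,11.8
scenario2,obesity1,2026,11.8
scenario2,obesity1,2027,11.8
scenario3,obesity1,2022,11.8
scenario3,obesity1,2023,11.8
scenario3,obesity1,2024,11.7
scenario3,obesity1,2025,11.6
scenario3,obesity1,2026,11.4
scenario3,obesity1,2027,11.2
status_quo,obesity2,2022,4.1
status_quo,obesity2,2023,4.1
status_quo,obesity2,2024,4.2
status_quo,obesity2,2025,4.3
status_quo,obesity2,2026,4.3
status_quo,obesity2,2027,4.4
scenario1,obesity2,2022,4.1
scenario1,obesity2,2023,4.3
scenario1,obesity2,2024,4.4
scenario1,obesity2,2025,4.5
scenario1,obesity2,2026,4.6
scenario1,obesity2,2027,4.6
scenario2,obesity2,2022,4.1
scenario2,obesity2,2023,4.3
scenario2,obesity2,2024,4.4
scenario2,obesity2,2025,4.5
scenario2,obesity2,2026,4.6
scenario2,obesity2,2027,4.6
scenario3,obesity2,2022,4.1
scenario3,obesity2,2023,4.2
scenario3,obesity2,2024,4.4
scenario3,obesity2,2025,4.4
scenario3,obesity2,2026,4.4
scenario3,obesity2,2027,4.3
status_quo,obesity3,2022,1.5
status_quo,obesity3,2023,1.5
status_quo,obesity3,2024,1.6
status_quo,obesity3,2025,1.6
status_quo,obesity3,2026,1.7
status_quo,obesity3,2027,1.7
scenario1,obesity3,2022,1.5
scenario1,obesity3,2023,1.4
scenario1,obesity3,2024,1.3
scenario1,obesity3,2025,1.2
scenario1,obesity3,2026,1.1
scenario1,obesity3,2027,1.0
scenario2,obesity3,2022,1.5
scenario2,obesity3,2023,1.4
scenario2,obesity3,2024,1.2
scenario2,obesity3,2025,1.1
scenario2,obesity3,2026,1.0
scenario2,obesity3,2027,0.9
scenario3,obesity3,2022,1.5
scenario3,obesity3,2023,1.4
scenario3,obesity3,2024,1.2
scenario3,obesity3,2025,1.1
scenario3,obesity3,2026,1.0
scenario3,obesity3,2027,0.9
status_quo,obesity_total,2022,17.3
status_quo,obesity_total,2027,18.2
scenario1,obesity_total,2022,17.3
scenario1,obesity_total,2027,17.3
scenario2,obesity_total,2022,17.3
scenario2,obesity_total,2027,17.3
scenario3,obesity_total,2022,17.3
scenario3,obesity_total,2027,16.4
status_quo,diabetes,2022,7.3
status_quo,diabetes,2023,7.5
status_quo,diabetes,2024,7.7
status_quo,diabetes,2025,7.8
status_quo,diabetes,2026,8.0
status_quo,diabetes,2027,8.1
scenario1,diabetes,2022,7.3
scenario1,diabetes,2023,7.5
scenario1,diabetes,2024,7.7
scenario1,diabetes,2025,7.8
scenario1,diabetes,2026,8.0
scenario1,diabetes,2027,8.1
scenario2,diabetes,2022,7.3
scenario2,diabetes,2023,7.5
scenario2,diabetes,2024,7.7
scenario2,diabetes,2025,7.8
scenario2,diabetes,2026,8.0
scenario2,diabetes,2027,8.1
scenario3,diabetes,2022,7.3
scenario3,diabetes,2023,7.5
scenario3,diabetes,2024,7.7
scenario3,diabetes,2025,7.8
scenario3,diabetes,2026,7.9
scenario3,diabetes,2027,8.1
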