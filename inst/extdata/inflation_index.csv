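year,index
2015,100.0
2016,103.2
2017,106.1
2018,108.3
2019,111.6
2020,115.1
2021,118.0
2022,122.9
2023,127.4
2024,131.1
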