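# UN-style geoscheme with explicit pins for every place in the packaged
# distribution table. User-editable; continent must be one of the seven
# standard names.
place	continent
Algeria	Africa
Argentina	South America
Brazil	South America
Canada	North America
China	Asia
Colombia	South America
Dominican Republic	North America
Ecuador	South America
Egypt	Africa
Ethiopia	Africa
Finland	Europe
France	Europe
Germany	Europe
Ghana	Africa
Guyana	South America
India	Asia
Indonesia	Asia
Iran	Asia
Iraq	Asia
Italy	Europe
Ivory Coast	Africa
Japan	Asia
King George Island	Antarctica
Lao	Asia
Malaysia	Asia
Myanmar	Asia
Netherlands	Europe
Papua New Guinea	Oceania
Poland	Europe
Portugal	Europe
Russia	Europe
Slovakia	Europe
South Africa	Africa
South Korea	Asia
Sri Lanka	Asia
Sweden	Europe
Thailand	Asia
Tunisia	Africa
USA	North America
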