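class,tag
Nature and wildlife appreciation,wildlife
Nature and wildlife appreciation,nature
Nature and wildlife appreciation,birds
Nature and wildlife appreciation,penguin
Nature and wildlife appreciation,whale
Nature and wildlife appreciation,puffin
Nature and wildlife appreciation,animals
Nature and wildlife appreciation,fauna
Nature and wildlife appreciation,naturelovers
Nature and wildlife appreciation,wildlifephotography
Nature and wildlife appreciation,forest
Nature and wildlife appreciation,endemic
Recreational (beach),beach
Recreational (beach),sand
Recreational (beach),swim
Recreational (beach),sun
Recreational (beach),surf
Recreational (beach),summer
Recreational (beach),holiday
Recreational (beach),vacation
Recreational (underwater),diving
Recreational (underwater),underwater
Recreational (underwater),scuba
Recreational (underwater),snorkeling
Recreational (underwater),coral
Recreational (underwater),reef
Recreational (underwater),ocean
Recreational (underwater),sealife
Recreational (hiking),hiking
Recreational (hiking),trekking
Recreational (hiking),trail
Recreational (hiking),camping
Recreational (hiking),outdoors
Recreational (hiking),walking
Aesthetic and wellbeing,beautiful
Aesthetic and wellbeing,amazing
Aesthetic and wellbeing,landscape
Aesthetic and wellbeing,sunset
Aesthetic and wellbeing,sunrise
Aesthetic and wellbeing,relax
Aesthetic and wellbeing,happy
Aesthetic and wellbeing,paradise
Aesthetic and wellbeing,sky
Aesthetic and wellbeing,landscapephotography
Aesthetic and wellbeing,art
Cultural heritage and identity,culture
Cultural heritage and identity,heritage
Cultural heritage and identity,history
Cultural heritage and identity,moai
Cultural heritage and identity,statue
Cultural heritage and identity,museum
Cultural heritage and identity,tradition
Wildlife conservation,conservation
Wildlife conservation,science
Wildlife conservation,sustainability
Wildlife conservation,savethereef
Wildlife conservation,ecology
Other (travel),travel
Other (travel),travelphotography
Other (travel),travelgram
Other (travel),instatravel
Other (travel),wanderlust
Other (travel),adventure
Other (travel),trip
Other (travel),tourism
Other (travel),explore
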