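species,family,length_bp,chromosome_spec,gc_percent,cds,trna,rrna,repeat_bp,mtpt_bp
Alnus glutinosa,Betulaceae,"629,389",16L,45.44,35,18,3,"8,581","29,856"
Betula pendula*,Betulaceae,"581,505",1L,45.52,36,19,3,"3,703","31,908"
Betula platyphylla,Betulaceae,"581,519",2L,45.53,36,19,3,"3,724","32,032"
Carpinus cordata,Betulaceae,"922,154",3C,44.97,34,20,3,"16,557","46,637"
Corylus avellana,Betulaceae,"635,030",2L,44.58,35,22,3,"39,128","60,416"
Ostrya chinensis,Betulaceae,"688,786",1L,45.23,34,18,3,"2,601","31,075"
Ostryopsis nobilis,Betulaceae,"669,332",1C,45.21,35,18,3,"4,810","24,710"
Casuarina equisetifolia,Casuarinaceae,"492,230",2C,44.15,35,23,3,"2,431","66,400"
Casuarina glauca,Casuarinaceae,"445,851",2C,44.92,34,19,3,"1,758","21,776"
Fagus sylvatica,Fagaceae,"504,715",1C,45.85,34,17,3,"2,702","4,615"
Castanea mollissima,Fagaceae,"388,038",1C,45.67,36,20,3,"10,888","10,169"
Lithocarpus fenestratus,Fagaceae,"485,396",6L,45.76,35,17,3,"13,254","7,122"
Quercus robur,Fagaceae,"390,878",1C,45.92,35,17,3,"22,006","8,140"
Quercus suber,Fagaceae,"478,989",1L,45.85,36,19,3,"26,635","4,967"
Quercus variabilis*,Fagaceae,"412,886",1C,45.76,36,17,3,"20,747","4,537"
Cyclocarya paliurus,Juglandaceae,"628,759",1C,44.89,37,19,3,"2,422","34,143"
Juglans cathayensis,Juglandaceae,"740,307",1C,45.16,37,20,3,"25,019","22,632"
Juglans hindsii,Juglandaceae,"716,397",1C,45.25,36,17,3,"2,118","12,514"
Juglans microcarpa,Juglandaceae,"623,287",1L,45.2,35,18,3,"6,984","12,448"
Juglans nigra,Juglandaceae,"716,680",1C,45.26,37,17,3,"2,022","12,667"
Juglans regia,Juglandaceae,"775,914",3L,45.19,35,17,3,"16,232","15,813"
Juglans sigillata,Juglandaceae,"778,034",1L,44.87,36,17,3,"19,731","34,425"
Platycarya strobilacea,Juglandaceae,"502,903",1C,45.26,37,19,3,"3,253","28,548"
Pterocarya stenoptera,Juglandaceae,"603,233",1L,45.35,36,17,3,"5,269","3,524"
Morella rubra,Myricaceae,"523,452",2C,45.33,38,18,3,"5,668","9,312"
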